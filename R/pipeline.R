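# Orchestration of the full comparative experiment: generate (or load) a
# dataset, stain-normalize to a reference, extract fused features and run the
# classical-classifier arms, train block-wise fine-tuned networks for the
# deep arms, score everything with the same metrics, and emit the comparison
# table plus embeddings and Grad-CAM maps for the best arm.

#' Experiment configuration
#'
#' @param design Dataset design data.frame (see [generate_dataset()]), or
#'   NULL when `manifest_path` points at an existing dataset.
#' @param manifest_path Optional path to an existing manifest CSV.
#' @param out_dir Output directory.
#' @param classifiers Character vector of classical arms
#'   (subset of knn, rf, mlp, adaboost, svm).
#' @param schedules Character vector of fine-tuning schedules, each a
#'   `tune_from` block id (subset of B6..B1).
#' @param magnifications Magnification factors to run (each fitted
#'   separately); NULL pools all records.
#' @param scheme `"binary"` (class column) or `"multiclass"` (subclass).
#' @param reference Path of the stain reference image, or NULL to use the
#'   first generated image; `normalize = FALSE` skips normalization.
#' @param image_size Generated patch side (square).
#' @param dl_input Network input side (divisible by 32).
#' @param scale_factor Network channel divisor for desk-scale runs.
#' @param epochs,k_folds,seed Protocol knobs.
#' @param normalize Whether to stain-normalize before both arms.
#' @param resize_features Feature-extraction resize target (NULL = native).
#' @return Object of class `experiment_config` (JSON round-trip stable).
#' @export
experiment_config <- function(design = NULL, manifest_path = NULL,
                              out_dir = tempfile("histopatch_run_"),
                              classifiers = c("knn", "rf"),
                              schedules = c("B6", "B3"),
                              magnifications = NULL,
                              scheme = c("binary", "multiclass"),
                              reference = NULL,
                              image_size = 32, dl_input = 32,
                              scale_factor = 8, epochs = 15, k_folds = 10,
                              seed = 1, normalize = FALSE,
                              resize_features = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(all(classifiers %in% c("knn", "rf", "mlp", "adaboost", "svm")),
            all(schedules %in% paste0("B", 1:6)))
  if (is.null(design) && is.null(manifest_path))
    stop("provide a design or a manifest_path")
  structure(list(design = design, manifest_path = manifest_path,
                 out_dir = out_dir, classifiers = classifiers,
                 schedules = schedules, magnifications = magnifications,
                 scheme = scheme, reference = reference,
                 image_size = image_size, dl_input = dl_input,
                 scale_factor = scale_factor, epochs = epochs,
                 k_folds = k_folds, seed = seed, normalize = normalize,
                 resize_features = resize_features),
            class = "experiment_config")
}

config_hash <- function(config) {
  # order-stable serialization; version-independent of attributes
  x <- unclass(config)
  x <- x[order(names(x))]
  paste0("h", sum(utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE,
                                             digits = NA, null = "null")) *
                    (seq_len(nchar(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                    digits = NA,
                                                    null = "null"))) %% 97 + 1)) %%
           .Machine$integer.max)
}

stage_done <- function(out_dir, stage, hash) {
  f <- file.path(out_dir, "stages", paste0(stage, ".json"))
  file.exists(f) &&
    identical(jsonlite::read_json(f)$hash, hash)
}

mark_stage <- function(out_dir, stage, hash) {
  dir.create(file.path(out_dir, "stages"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(list(stage = stage, hash = hash),
                       file.path(out_dir, "stages", paste0(stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the full comparative experiment
#'
#' Stages: dataset generation (or loading), optional stain normalization,
#' fused-feature extraction + classical arms under stratified k-fold CV,
#' deep arms (one block-wise schedule each, 70/30 split), and PCA embedding
#' plus Grad-CAM heatmaps for the best deep arm. Completed stages are skipped
#' when re-run with an unchanged configuration. A failing arm is recorded in
#' the report with its error; independent arms still run.
#'
#' @param config An [experiment_config()].
#' @return Object of class `comparison_report`: data.frame `table` with one
#'   row per (arm, scheme, magnification), plus provenance.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed

  # --- stage: dataset ---------------------------------------------------
  data_dir <- file.path(out_dir, "data")
  if (!is.null(config$manifest_path)) {
    manifest <- read_manifest(config$manifest_path)
    data_dir <- dirname(config$manifest_path)
  } else {
    if (!stage_done(out_dir, "dataset", hash)) {
      generate_dataset(config$design, data_dir,
                       seed = derive_seed(seed, "dataset"),
                       size = c(config$image_size, config$image_size))
      mark_stage(out_dir, "dataset", hash)
    }
    manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  }

  # --- stage: stain normalization --------------------------------------
  if (isTRUE(config$normalize)) {
    norm_dir <- file.path(out_dir, "normalized")
    if (!stage_done(out_dir, "normalize", hash)) {
      ref <- config$reference %||%
        file.path(data_dir, manifest$image_path[1])
      normalize_manifest(manifest, data_dir, ref, norm_dir,
                         seed = derive_seed(seed, "normalize"))
      mark_stage(out_dir, "normalize", hash)
    }
    data_dir <- norm_dir
  }

  label_col <- if (config$scheme == "binary") "class" else "subclass"
  mags <- config$magnifications
  if (is.null(mags)) mags <- NA
  rows <- list()
  add_row <- function(arm, kind, mag, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      arm = arm, kind = kind, scheme = config$scheme,
      magnification = as.character(mag),
      accuracy = res$accuracy %||% NA_real_,
      recall = res$recall %||% NA_real_,
      precision = res$precision %||% NA_real_,
      status = res$status, error = res$error %||% "",
      stringsAsFactors = FALSE)
  }

  for (mag in mags) {
    sub <- if (is.na(mag)) manifest else
      manifest[manifest$magnification == mag, , drop = FALSE]
    labels <- as.character(sub[[label_col]])

    # --- classical arms ---------------------------------------------
    if (length(config$classifiers)) {
      feat_file <- file.path(out_dir, paste0("features_", mag, ".csv"))
      if (!stage_done(out_dir, paste0("features_", mag), hash)) {
        feats <- extract_features(sub, data_dir,
                                  resize_to = config$resize_features)
        utils::write.csv(feats, feat_file, row.names = FALSE)
        mark_stage(out_dir, paste0("features_", mag), hash)
      }
      feats <- utils::read.csv(feat_file, stringsAsFactors = FALSE)
      fx <- as.matrix(feats[, 1:550])
      for (cl in config$classifiers) {
        res <- tryCatch({
          folds <- make_folds(labels, k = config$k_folds,
                              seed = derive_seed(seed, paste0("folds", mag)))
          rep <- train_eval(fx, labels, classifier_spec(cl), folds,
                            seed = derive_seed(seed, paste0(cl, mag)))
          list(accuracy = rep$accuracy, recall = rep$recall,
               precision = rep$precision, status = "ok")
        }, error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
        add_row(paste0("cml:", cl), "CML", mag, res)
      }
    }

    # --- deep arms ---------------------------------------------------
    if (length(config$schedules)) {
      loaded <- load_manifest_images(sub, data_dir, size = config$dl_input)
      set.seed(derive_seed(seed, paste0("dlsplit", mag)))
      n <- length(loaded$labels)
      tr_idx <- sort(sample.int(n, round(0.7 * n)))
      te_idx <- setdiff(seq_len(n), tr_idx)
      for (sch in config$schedules) {
        res <- tryCatch({
          lab_tr <- if (config$scheme == "binary") loaded$labels[tr_idx] else
            as.character(sub$subclass)[tr_idx]
          lab_te <- if (config$scheme == "binary") loaded$labels[te_idx] else
            as.character(sub$subclass)[te_idx]
          net <- build_network(length(unique(c(lab_tr, lab_te))),
                               scale_factor = config$scale_factor,
                               input_size = config$dl_input,
                               seed = derive_seed(seed, paste0("init", sch, mag)))
          net <- apply_blockwise_schedule(net, sch)
          fit <- train_network(net, loaded$x[, , , tr_idx, drop = FALSE],
                               lab_tr,
                               train_config(epochs = config$epochs,
                                            seed = derive_seed(seed, paste0("train", sch, mag))))
          pred <- predict(fit$net, loaded$x[, , , te_idx, drop = FALSE])
          m <- compute_metrics(lab_te, pred,
                               sort(unique(c(lab_tr, lab_te))))
          saveRDS(fit$net, file.path(out_dir, paste0("net_", sch, "_", mag, ".rds")))
          list(accuracy = m$accuracy, recall = m$recall,
               precision = m$precision, status = "ok")
        }, error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
        add_row(paste0("dl:", sch), "DL", mag, res)
      }
    }
  }

  table <- do.call(rbind, rows)
  report <- structure(list(table = table, config = config,
                           config_hash = hash, seed = seed),
                      class = "comparison_report")
  utils::write.csv(table, file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(table, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # --- visual explanation for the best arm -----------------------------
  ok <- table[table$status == "ok", , drop = FALSE]
  if (nrow(ok)) {
    best <- select_best(report, config$scheme, mags[1])
    feat_file <- file.path(out_dir, paste0("features_", mags[1], ".csv"))
    if (file.exists(feat_file)) {
      feats <- utils::read.csv(feat_file, stringsAsFactors = FALSE)
      emb <- pca_2d(as.matrix(feats[, 1:550]),
                    labels = feats[[label_col]])
      utils::write.csv(data.frame(emb$points, label = feats[[label_col]]),
                       file.path(out_dir, "embedding_pca.csv"),
                       row.names = FALSE)
    }
    report$best_arm <- best
  }
  report
}

#' Select the best arm of a comparison report
#'
#' Maximum accuracy; ties broken by higher macro recall (the rule used when
#' two fine-tuned architectures score identically), remaining ties by
#' lexicographic arm id.
#'
#' @param report A `comparison_report` (or its `table`).
#' @param scheme `"binary"` or `"multiclass"`.
#' @param magnification Magnification cell to inspect (NA for pooled runs).
#' @return The winning arm id (character).
#' @export
select_best <- function(report, scheme, magnification = NA) {
  tab <- if (inherits(report, "comparison_report")) report$table else report
  sel <- tab$scheme == scheme & tab$status == "ok" &
    (is.na(magnification) | tab$magnification == as.character(magnification))
  cells <- tab[sel, , drop = FALSE]
  if (!nrow(cells)) stop("no successful cells for the requested scheme/magnification")
  ord <- order(-cells$accuracy, -cells$recall, cells$arm)
  cells$arm[ord[1]]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report (scheme:", x$config$scheme, ")\n")
  print(x$table[, c("arm", "magnification", "accuracy", "recall",
                    "precision", "status")], row.names = FALSE)
  if (!is.null(x$best_arm)) cat("best arm:", x$best_arm, "\n")
  invisible(x)
}
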
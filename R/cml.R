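# Classical classification of fused handcrafted features under stratified
# k-fold cross-validation with a per-fold validation split.
#
# Five classifiers: k-nearest neighbours (k = 3, Euclidean, deterministic
# lowest-class-index tie-break), random forest (100 trees), a one-hidden-layer
# multilayer perceptron (100 ReLU units, Adam, L2 1e-4), AdaBoost (SAMME over
# depth-1 decision stumps, 50 rounds, learning rate 1) and a linear SVM
# (C = 5). Features are standardized on each fold's training portion only.

#' Classifier specification with the study's default hyperparameters
#'
#' @param kind One of `"knn"`, `"rf"`, `"mlp"`, `"adaboost"`, `"svm"`.
#' @param ... Overrides of the defaults listed below.
#' @return Object of class `classifier_spec` (JSON round-trip stable).
#'
#' @details Defaults: knn `k = 3` (Euclidean metric, configurable); rf
#'   `ntree = 100`; mlp one hidden layer of `hidden = 100` rectified-linear
#'   units, Adam optimizer, `l2 = 1e-4`, `learning_rate = 1e-3`,
#'   `max_iter = 2000`; adaboost `n_estimators = 50`, `learning_rate = 1`;
#'   svm linear kernel with `cost = 5`.
#' @export
classifier_spec <- function(kind = c("knn", "rf", "mlp", "adaboost", "svm"),
                            ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 3, metric = "euclidean"),
    rf = list(ntree = 100),
    mlp = list(hidden = 100, l2 = 1e-4, learning_rate = 1e-3,
               max_iter = 2000, batch_size = 200, tol = 1e-4,
               n_iter_no_change = 10),
    adaboost = list(n_estimators = 50, learning_rate = 1),
    svm = list(cost = 5, kernel = "linear"))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown hyperparameters for ", kind, ": ",
                        paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(list(kind = kind, hyperparameters = defaults),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier:", x$kind, "\n")
  hp <- x$hyperparameters
  cat(paste0("  ", names(hp), " = ", unlist(hp), collapse = "\n"), "\n")
  invisible(x)
}

#' Stratified k-fold split with per-fold validation portion
#'
#' Each class's indices are shuffled and dealt round-robin into `k` folds, so
#' fold sizes differ by at most one and per-fold class proportions stay
#' within one record of the global proportions. For each fold, the remaining
#' records form the training portion, `val_frac` of which (stratified) is set
#' aside as a validation set.
#'
#' @param labels Vector of class labels (or a manifest data.frame, in which
#'   case its `class` column is used).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param val_frac Fraction of each training portion held out for validation
#'   (default 0.3).
#' @return Object of class `fold_split`: list of `k` folds, each with
#'   `train`, `validation`, `test` index vectors.
#' @export
make_folds <- function(labels, k = 10, seed = 1, val_frac = 0.3) {
  if (is.data.frame(labels)) labels <- labels$class
  labels <- as.character(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class(es) with fewer than k=", k, " records: ",
         paste(names(counts)[counts < k], collapse = ", "))
  }
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  load <- integer(k)
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    r <- n_c %% k
    per_fold <- rep(base, k)
    if (r > 0) {
      # spill the remainder into the currently smallest folds, so overall
      # fold sizes never differ by more than one record
      extras <- order(load, seq_len(k))[seq_len(r)]
      per_fold[extras] <- per_fold[extras] + 1L
    }
    fold_of[idx] <- rep(seq_len(k), per_fold)
    load <- load + per_fold
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    rest <- which(fold_of != f)
    val <- integer(0)
    for (cl in names(counts)) {
      cl_rest <- intersect(rest, which(labels == cl))
      n_val <- round(val_frac * length(cl_rest))
      val <- c(val, sample(cl_rest, n_val))
    }
    list(train = setdiff(rest, val), validation = sort(val), test = test)
  })
  structure(list(folds = folds, k = k, seed = seed, val_frac = val_frac,
                 n = n), class = "fold_split")
}

#' Classification metrics from true and predicted labels
#'
#' Accuracy, macro-averaged recall and precision (percent), and the
#' confusion matrix (true classes in rows, predictions in columns). Classes
#' with no true (respectively predicted) instances contribute recall
#' (precision) of 0 to the macro average.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_set Label universe (default: union of observed labels).
#' @return List with `accuracy`, `recall`, `precision` (percent) and
#'   `confusion`.
#' @export
compute_metrics <- function(y_true, y_pred, class_set = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(class_set)) class_set <- sort(unique(c(as.character(y_true),
                                                     as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = class_set)
  y_pred <- factor(as.character(y_pred), levels = class_set)
  if (anyNA(y_true) || anyNA(y_pred)) stop("labels outside class_set")
  cm <- table(true = y_true, predicted = y_pred)
  acc <- sum(diag(cm)) / sum(cm) * 100
  rec <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), 0) * 100
  prec <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0) * 100
  list(accuracy = acc, recall = mean(rec), precision = mean(prec),
       confusion = cm)
}

# ---- individual classifiers -------------------------------------------------

# KNN with deterministic tie handling: neighbour ties at the k-th distance are
# resolved by lowest training index; voting ties by smallest class index.
knn_fit <- function(x, y, spec) {
  list(x = x, y = as.character(y), k = spec$hyperparameters$k,
       classes = sort(unique(as.character(y))))
}

knn_predict <- function(model, newx) {
  tr <- model$x
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(newx)), rowSums(tr^2)) - 2 * newx %*% t(tr)
  apply(d2, 1, function(di) {
    nn <- order(di)[seq_len(model$k)]   # order() breaks ties by index
    votes <- table(factor(model$y[nn], levels = model$classes))
    model$classes[which.max(votes)]     # which.max: smallest class index wins
  })
}

# AdaBoost (SAMME) over depth-1 rpart stumps. SAMME supports K >= 2 classes:
# alpha_t = lr * (log((1 - err) / err) + log(K - 1)).
adaboost_fit <- function(x, y, spec, seed = 1) {
  y <- factor(as.character(y))
  K <- nlevels(y)
  n <- nrow(x)
  hp <- spec$hyperparameters
  df <- data.frame(y = y, x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  set.seed(as.integer(seed))
  for (t in seq_len(hp$n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2,
                                                       xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break           # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- hp$learning_rate * (log((1 - err) / err) + log(K - 1))
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break                # perfect stump: done
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, classes = levels(y))
}

adaboost_predict <- function(model, newx) {
  df <- data.frame(newx)
  scores <- matrix(0, nrow(newx), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (t in seq_along(model$stumps)) {
    pred <- as.character(predict(model$stumps[[t]], df, type = "class"))
    scores[cbind(seq_len(nrow(newx)), match(pred, model$classes))] <-
      scores[cbind(seq_len(nrow(newx)), match(pred, model$classes))] +
      model$alphas[t]
  }
  model$classes[apply(scores, 1, which.max)]
}

# One-hidden-layer MLP (ReLU, softmax output) trained by Adam with L2
# penalty; early stopping on training-loss plateau, validation monitoring.
mlp_fit <- function(x, y, spec, xval = NULL, yval = NULL, seed = 1) {
  hp <- spec$hyperparameters
  y <- factor(as.character(y))
  classes <- levels(y)
  K <- length(classes)
  n <- nrow(x); p <- ncol(x); Hn <- hp$hidden
  set.seed(as.integer(seed))
  W1 <- matrix(stats::rnorm(p * Hn, 0, sqrt(2 / p)), Hn, p)
  b1 <- numeric(Hn)
  W2 <- matrix(stats::rnorm(Hn * K, 0, sqrt(2 / Hn)), K, Hn)
  b2 <- numeric(K)
  yi <- as.integer(y)
  mW1 <- vW1 <- W1 * 0; mb1 <- vb1 <- b1 * 0
  mW2 <- vW2 <- W2 * 0; mb2 <- vb2 <- b2 * 0
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- hp$learning_rate; l2 <- hp$l2
  bs <- min(hp$batch_size, n)
  best_loss <- Inf; stall <- 0; step <- 0
  for (epoch in seq_len(hp$max_iter)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = bs)) {
      bi <- ord[start:min(start + bs - 1, n)]
      xb <- t(x[bi, , drop = FALSE])           # p x b
      a1 <- W1 %*% xb + b1                     # Hn x b
      h1 <- pmax(a1, 0)
      z <- W2 %*% h1 + b2                      # K x b
      z <- sweep(z, 2, apply(z, 2, max))
      ez <- exp(z); probs <- sweep(ez, 2, colSums(ez), "/")
      yb <- yi[bi]
      ep_loss <- ep_loss - sum(log(probs[cbind(yb, seq_along(bi))] + 1e-12))
      dz <- probs
      dz[cbind(yb, seq_along(bi))] <- dz[cbind(yb, seq_along(bi))] - 1
      dz <- dz / length(bi)
      gW2 <- dz %*% t(h1) + l2 * W2; gb2 <- rowSums(dz)
      dh1 <- crossprod(W2, dz) * (a1 > 0)
      gW1 <- dh1 %*% t(xb) + l2 * W1; gb1 <- rowSums(dh1)
      step <- step + 1
      upd <- function(m, v, g) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^step); vh <- v / (1 - beta2^step)
        list(m = m, v = v, d = lr * mh / (sqrt(vh) + adam_eps))
      }
      u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$d
      u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$d
      u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$d
      u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$d
    }
    ep_loss <- ep_loss / n
    if (ep_loss > best_loss - hp$tol) stall <- stall + 1 else stall <- 0
    best_loss <- min(best_loss, ep_loss)
    if (stall >= hp$n_iter_no_change) break
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes)
}

mlp_predict <- function(model, newx) {
  h1 <- pmax(model$W1 %*% t(newx) + model$b1, 0)
  z <- model$W2 %*% h1 + model$b2
  model$classes[apply(z, 2, which.max)]
}

train_classifier <- function(spec, x, y, xval = NULL, yval = NULL, seed = 1) {
  switch(spec$kind,
    knn = knn_fit(x, y, spec),
    rf = {
      set.seed(as.integer(seed))
      randomForest::randomForest(x, factor(as.character(y)),
                                 ntree = spec$hyperparameters$ntree)
    },
    mlp = mlp_fit(x, y, spec, xval, yval, seed = seed),
    adaboost = adaboost_fit(x, y, spec, seed = seed),
    svm = {
      set.seed(as.integer(seed))
      e1071::svm(x, factor(as.character(y)), kernel = "linear",
                 cost = spec$hyperparameters$cost, scale = FALSE)
    })
}

predict_classifier <- function(spec, model, newx) {
  switch(spec$kind,
    knn = knn_predict(model, newx),
    rf = as.character(predict(model, newx)),
    mlp = mlp_predict(model, newx),
    adaboost = adaboost_predict(model, newx),
    svm = as.character(predict(model, newx)))
}

#' Cross-validated training and evaluation of one classifier
#'
#' Per fold: feature standardization (zero mean, unit variance) is fitted on
#' the training portion only and applied to validation and test; the
#' classifier is fitted on the training portion (the validation portion is
#' used for MLP monitoring only); the held-out fold is predicted and scored.
#'
#' @param features Numeric matrix or data.frame of features, rows aligned
#'   with `labels`; must be finite.
#' @param labels Class labels.
#' @param spec A [classifier_spec()].
#' @param folds A [make_folds()] split.
#' @param seed Integer seed for the per-fold fits.
#' @return Object of class `cml_report`: per-fold and mean accuracy, macro
#'   recall, macro precision (percent), pooled confusion matrix.
#' @export
train_eval <- function(features, labels, spec, folds, seed = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    stop("non-finite feature values in rows: ",
         paste(utils::head(which(rowSums(!is.finite(x)) > 0), 10),
               collapse = ", "))
  }
  labels <- as.character(labels)
  class_set <- sort(unique(labels))
  per_fold <- data.frame(fold = seq_len(folds$k), accuracy = NA_real_,
                         recall = NA_real_, precision = NA_real_)
  pooled <- NULL
  for (f in seq_len(folds$k)) {
    fd <- folds$folds[[f]]
    mu <- colMeans(x[fd$train, , drop = FALSE])
    sg <- apply(x[fd$train, , drop = FALSE], 2, stats::sd)
    sg[sg < 1e-12] <- 1
    scale_x <- function(idx) sweep(sweep(x[idx, , drop = FALSE], 2, mu), 2, sg, "/")
    xtr <- scale_x(fd$train); xva <- scale_x(fd$validation)
    xte <- scale_x(fd$test)
    model <- train_classifier(spec, xtr, labels[fd$train],
                              xva, labels[fd$validation],
                              seed = derive_seed(seed, paste0("fold", f)))
    pred <- predict_classifier(spec, model, xte)
    m <- compute_metrics(labels[fd$test], pred, class_set)
    per_fold$accuracy[f] <- m$accuracy
    per_fold$recall[f] <- m$recall
    per_fold$precision[f] <- m$precision
    pooled <- if (is.null(pooled)) m$confusion else pooled + m$confusion
  }
  structure(list(spec = spec, per_fold = per_fold,
                 accuracy = mean(per_fold$accuracy),
                 recall = mean(per_fold$recall),
                 precision = mean(per_fold$precision),
                 confusion = pooled, seed = seed, k = folds$k),
            class = "cml_report")
}

#' @export
print.cml_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, classifier %s\n", x$k, x$spec$kind))
  cat(sprintf("  accuracy %.2f%%  macro recall %.2f%%  macro precision %.2f%%\n",
              x$accuracy, x$recall, x$precision))
  cat("pooled confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
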
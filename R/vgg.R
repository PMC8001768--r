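# VGG-19-style network: sixteen 3x3 convolution layers in the 2-2-4-4-4
# pattern interleaved with five 2x2 max-pools, followed by three fully
# connected layers (4096, 4096, num_classes) — 19 weight-bearing layers.
# The architecture is partitioned into six blocks: B1..B5 the convolutional
# groups, B6 the dense head; block-wise fine-tuning freezes a leading run of
# blocks and trains the rest. A `scale_factor` divides every channel width
# (minimum 1) for miniature desk-scale instances while preserving the layer
# count, pattern and partition.

vgg_channel_plan <- function(scale_factor) {
  base <- list(B1 = c(64, 64), B2 = c(128, 128),
               B3 = rep(256, 4), B4 = rep(512, 4), B5 = rep(512, 4))
  lapply(base, function(v) pmax(1L, as.integer(v / scale_factor)))
}

#' Build a VGG-19-style network
#'
#' @param num_classes Number of output classes (>= 2); the final fully
#'   connected layer has this width.
#' @param scale_factor Integer >= 1; channel widths (and the 4096-wide dense
#'   layers) are divided by it for miniature instances. The weight-layer
#'   count (19), layer pattern and six-block partition are unchanged.
#' @param input_size Square input side in pixels; must be divisible by 32
#'   (five 2x2 pools). Default 224.
#' @param dropout Dropout probability on the two hidden dense layers.
#' @param seed Seed for the He-style random initialization (used when no
#'   pretrained weights are supplied).
#' @param weights_file Optional RDS file with a previously saved network
#'   whose weights are copied in (shapes must match).
#' @return Object of class `vgg_network`.
#' @export
build_network <- function(num_classes, scale_factor = 1, input_size = 224,
                          dropout = 0.5, seed = 1, weights_file = NULL) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (scale_factor < 1 || scale_factor != round(scale_factor))
    stop("scale_factor must be a positive integer")
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  set.seed(as.integer(seed))
  plan <- vgg_channel_plan(scale_factor)
  fc_width <- max(1L, as.integer(4096 / scale_factor))
  layers <- list()
  cin <- 3L
  conv_id <- 0
  he_conv <- function(cin, cout) {
    matrix(stats::rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))), cout, 9 * cin)
  }
  for (blk in names(plan)) {
    for (cout in plan[[blk]]) {
      conv_id <- conv_id + 1
      layers[[length(layers) + 1]] <- list(
        type = "conv", W = he_conv(cin, cout), b = numeric(cout),
        block = blk, trainable = TRUE, name = sprintf("conv%d", conv_id))
      layers[[length(layers) + 1]] <- list(type = "relu")
      cin <- cout
    }
    layers[[length(layers) + 1]] <- list(type = "pool")
  }
  layers[[length(layers) + 1]] <- list(type = "flatten")
  spatial <- input_size / 32
  fc_in <- as.integer(spatial^2 * cin)
  he_fc <- function(n_in, n_out) {
    matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
  }
  fc_dims <- list(c(fc_in, fc_width), c(fc_width, fc_width),
                  c(fc_width, as.integer(num_classes)))
  for (j in 1:3) {
    layers[[length(layers) + 1]] <- list(
      type = "fc", W = he_fc(fc_dims[[j]][1], fc_dims[[j]][2]),
      b = numeric(fc_dims[[j]][2]), block = "B6", trainable = TRUE,
      name = sprintf("fc%d", j))
    if (j < 3) {
      layers[[length(layers) + 1]] <- list(type = "relu")
      layers[[length(layers) + 1]] <- list(type = "dropout", p = dropout)
    }
  }
  net <- structure(list(layers = layers, num_classes = as.integer(num_classes),
                        scale_factor = as.integer(scale_factor),
                        input_size = as.integer(input_size),
                        classes = NULL, seed = as.integer(seed)),
                   class = "vgg_network")
  if (!is.null(weights_file)) {
    saved <- readRDS(weights_file)
    wi <- weight_layer_indices(net)
    for (i in wi) {
      if (!identical(dim(saved$layers[[i]]$W), dim(net$layers[[i]]$W)))
        stop("weight shapes in ", weights_file, " do not match this network")
      net$layers[[i]]$W <- saved$layers[[i]]$W
      net$layers[[i]]$b <- saved$layers[[i]]$b
    }
  }
  net
}

weight_layer_indices <- function(net) {
  which(vapply(net$layers, function(l) l$type %in% c("conv", "fc"), logical(1)))
}

#' Count of weight-bearing layers (16 conv + 3 fully connected = 19)
#' @param net A `vgg_network`.
#' @return Integer.
#' @export
n_weight_layers <- function(net) length(weight_layer_indices(net))

#' Apply a block-wise fine-tuning schedule
#'
#' Blocks `tune_from` .. B6 become trainable; blocks before `tune_from` are
#' frozen. `tune_from = "B6"` trains only the dense head; `tune_from = "B1"`
#' is full fine-tuning.
#'
#' @param net A `vgg_network`.
#' @param tune_from Block id in `B1` .. `B6`.
#' @return The network with `trainable` flags set; the per-layer freeze mask
#'   is attached as attribute `"freeze_mask"`.
#' @export
apply_blockwise_schedule <- function(net, tune_from = "B6") {
  blocks <- paste0("B", 1:6)
  if (!tune_from %in% blocks) stop("tune_from must be one of B1..B6")
  cut <- match(tune_from, blocks)
  mask <- list()
  for (i in weight_layer_indices(net)) {
    ly <- net$layers[[i]]
    trainable <- match(ly$block, blocks) >= cut
    net$layers[[i]]$trainable <- trainable
    mask[[length(mask) + 1]] <- list(name = ly$name, block = ly$block,
                                     trainable = trainable,
                                     n_params = length(ly$W) + length(ly$b))
  }
  attr(net, "freeze_mask") <- mask
  net
}

#' Number of trainable parameters under the current schedule
#' @param net A `vgg_network`.
#' @return Integer count.
#' @export
count_trainable_params <- function(net) {
  sum(vapply(net$layers[weight_layer_indices(net)], function(l) {
    if (isTRUE(l$trainable)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

#' Draw one of the six training augmentations
#'
#' The augmentation set is {identity, horizontal flip, vertical flip,
#' rotation by 90, 180, 270 degrees}; each epoch every training image gets
#' one seeded uniform draw. All six are pixel permutations, so the pixel
#' multiset is preserved exactly.
#'
#' @param image `H x W x C` array (square for the rotations).
#' @param transform Integer 1..6 to apply a specific transform, or NULL to
#'   draw one uniformly (using the current RNG state, or `seed` if given).
#' @param seed Optional seed for the draw.
#' @return Transformed image array.
#' @export
augment_image <- function(image, transform = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(transform)) transform <- sample.int(6, 1)
  if (transform != 1 && transform <= 6 && transform >= 4 &&
      dim(image)[1] != dim(image)[2])
    stop("rotations require a square image")
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  app <- function(f) {
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- f(image[, , ch])
    out
  }
  switch(transform,
         image,                                            # identity
         app(function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]),  # h-flip
         app(function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]),  # v-flip
         {
           out <- array(0, dim(image)[c(2, 1, 3)])
           for (ch in seq_len(dim(image)[3])) out[, , ch] <- rot90(image[, , ch])
           out
         },
         app(function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]),
         {
           out <- array(0, dim(image)[c(2, 1, 3)])
           for (ch in seq_len(dim(image)[3]))
             out[, , ch] <- rot90(rot90(rot90(image[, , ch])))
           out
         })
}

#' Training configuration
#'
#' SGD with momentum 0.9, constant learning rate 0.001, dropout 0.5 on the
#' dense head, weight decay 0.001 (weights only, not biases), batch size 32,
#' 70 epochs.
#'
#' @param epochs,batch_size,learning_rate,momentum,weight_decay,seed,augment
#'   Self-describing; defaults as above.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 70, batch_size = 32, learning_rate = 0.001,
                         momentum = 0.9, weight_decay = 0.001, seed = 1,
                         augment = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Train a network by SGD with momentum
#'
#' Cross-entropy loss on softmax outputs. Frozen layers receive no updates
#' and are bit-identical before and after training. One augmentation
#' transform is drawn per sample per epoch when `config$augment` is TRUE.
#'
#' @param net A `vgg_network` (schedule already applied).
#' @param x `H x W x 3 x N` input array (normalized; see
#'   [load_manifest_images()]).
#' @param y Class labels (factor or character), length N.
#' @param config A [train_config()].
#' @param x_test,y_test Optional held-out set; per-epoch test accuracy is
#'   logged in the history when supplied.
#' @param max_restarts Deep stacks trained from random initialization
#'   without normalization layers occasionally never leave chance level.
#'   When > 0, a run whose final training accuracy is below
#'   `restart_threshold` is restarted with freshly drawn trainable weights
#'   and a derived seed, up to this many times. Deterministic for a fixed
#'   `config$seed`. Default 0 (single run).
#' @param restart_threshold Training-accuracy percentage below which a run
#'   counts as failed-to-train (used only when `max_restarts > 0`).
#' @param restart_scope `"trainable"` redraws only the trainable layers on
#'   restart (keeps frozen layers, e.g. pretrained weights); `"all"` also
#'   redraws frozen layers — the right choice when the whole network
#'   started from random initialization, since a degenerate random draw in
#'   a frozen early block starves every downstream attempt.
#' @return List of class `vgg_fit`: `net` (trained), `history` data.frame
#'   with one row per epoch (`loss`, `train_accuracy`, `test_accuracy`),
#'   and `restarts` (restarts actually used).
#' @export
train_network <- function(net, x, y, config = train_config(),
                          x_test = NULL, y_test = NULL,
                          max_restarts = 0, restart_threshold = 60,
                          restart_scope = c("trainable", "all")) {
  restart_scope <- match.arg(restart_scope)
  fit <- train_network_once(net, x, y, config, x_test, y_test)
  fit$restarts <- 0
  attempt <- 0
  while (max_restarts > 0 && attempt < max_restarts &&
         utils::tail(fit$history$train_accuracy, 1) < restart_threshold) {
    attempt <- attempt + 1
    net_r <- reinit_weights(net, derive_seed(config$seed,
                                             paste0("restart", attempt)),
                            scope = restart_scope)
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, paste0("restart-train", attempt))
    fit <- train_network_once(net_r, x, y, cfg_r, x_test, y_test)
    fit$restarts <- attempt
  }
  fit
}

# Redraw He-style weights across restarts. Scope "trainable" keeps frozen
# layers (appropriate when they hold pretrained weights); scope "all" also
# redraws frozen layers, which matters when the whole network started from
# random initialization: a degenerate random draw in a frozen early block
# feeds uninformative features to every downstream attempt, and no redraw
# of the trainable layers can repair it.
reinit_weights <- function(net, seed, scope = "trainable") {
  set.seed(as.integer(seed))
  for (i in weight_layer_indices(net)) {
    ly <- net$layers[[i]]
    if (scope == "trainable" && !isTRUE(ly$trainable)) next
    fan_in <- ncol(ly$W)
    net$layers[[i]]$W <- matrix(stats::rnorm(length(ly$W), 0,
                                             sqrt(2 / fan_in)),
                                nrow(ly$W), ncol(ly$W))
    net$layers[[i]]$b <- ly$b * 0
  }
  net
}

train_network_once <- function(net, x, y, config, x_test = NULL,
                               y_test = NULL) {
  y <- factor(as.character(y))
  if (is.null(net$classes)) net$classes <- levels(y)
  yi <- match(as.character(y), net$classes)
  if (anyNA(yi)) stop("labels outside the network's class set")
  n <- dim(x)[4]
  if (n == 0) stop("empty training set")
  set.seed(config$seed)
  wi <- weight_layer_indices(net)
  vel <- lapply(net$layers[wi], function(l) list(W = l$W * 0, b = l$b * 0))
  hist_rows <- list()
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[, , , bi, drop = FALSE]
      if (config$augment) {
        for (j in seq_along(bi)) {
          tr <- sample.int(6, 1)
          if (tr > 1) xb[, , , j] <- augment_image(xb[, , , j], transform = tr)
        }
      }
      fw <- nn_forward(net, xb, training = TRUE)
      probs <- softmax_probs(fw$logits)
      picked <- probs[cbind(yi[bi], seq_along(bi))]
      ep_loss <- ep_loss - sum(log(picked + 1e-12))
      ep_correct <- ep_correct + sum(apply(fw$logits, 2, which.max) == yi[bi])
      dlogits <- probs
      dlogits[cbind(yi[bi], seq_along(bi))] <-
        dlogits[cbind(yi[bi], seq_along(bi))] - 1
      dlogits <- dlogits / length(bi)
      bw <- nn_backward(net, fw$cache, dlogits)
      for (k in seq_along(wi)) {
        i <- wi[k]
        if (!isTRUE(net$layers[[i]]$trainable)) next
        g <- bw$grads[[i]]
        vel[[k]]$W <- config$momentum * vel[[k]]$W -
          config$learning_rate * (g$gW + config$weight_decay * net$layers[[i]]$W)
        vel[[k]]$b <- config$momentum * vel[[k]]$b - config$learning_rate * g$gb
        net$layers[[i]]$W <- net$layers[[i]]$W + vel[[k]]$W
        net$layers[[i]]$b <- net$layers[[i]]$b + vel[[k]]$b
      }
    }
    row <- data.frame(epoch = epoch, loss = ep_loss / n,
                      train_accuracy = ep_correct / n * 100,
                      test_accuracy = NA_real_)
    if (!is.null(x_test)) {
      pred <- predict(net, x_test, type = "class")
      row$test_accuracy <- mean(pred == as.character(y_test)) * 100
    }
    hist_rows[[epoch]] <- row
  }
  structure(list(net = net, history = do.call(rbind, hist_rows),
                 config = config), class = "vgg_fit")
}

#' @export
predict.vgg_network <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  logits <- nn_forward(object, x, training = FALSE)$logits
  probs <- softmax_probs(logits)
  classes <- object$classes %||% as.character(seq_len(object$num_classes))
  if (type == "prob") {
    t(structure(probs, dimnames = list(classes, NULL)))
  } else {
    classes[apply(logits, 2, which.max)]
  }
}

#' Deep features from the penultimate dense layer
#'
#' Activations of the second hidden fully connected layer (width 4096 at
#' scale 1), taken after the rectifier with dropout disabled.
#'
#' @param net A trained `vgg_network`.
#' @param x `H x W x 3 x N` input array at the network's input size.
#' @return `N x width` matrix of non-negative activations.
#' @export
extract_deep_features <- function(net, x) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] != net$input_size || dim(x)[2] != net$input_size)
    stop("images must match the network input size ", net$input_size)
  fw <- nn_forward(net, x, training = FALSE)
  fc_idx <- which(vapply(net$layers,
                         function(l) l$type == "fc", logical(1)))
  relu_after_fc2 <- fc_idx[2] + 1   # fc2 -> relu
  stopifnot(net$layers[[relu_after_fc2]]$type == "relu")
  t(fw$cache[[relu_after_fc2]]$out)
}

#' Load, resize and normalize the images of a manifest for network input
#'
#' Per-channel normalization to mean 0.5 / std 0.5 (values in roughly
#' [-1, 1]), the from-scratch training convention.
#'
#' @param manifest Manifest data.frame.
#' @param base_dir Directory against which image paths resolve.
#' @param size Square side in pixels (must match the network input size).
#' @return List with `x` (`size x size x 3 x N` array) and `labels`.
#' @export
load_manifest_images <- function(manifest, base_dir, size = 32) {
  n <- nrow(manifest)
  x <- array(0, c(size, size, 3, n))
  for (i in seq_len(n)) {
    img <- read_image_rgb(file.path(base_dir, manifest$image_path[i]))
    if (dim(img)[1] != size || dim(img)[2] != size)
      img <- resize_rgb(img, size, size)
    x[, , , i] <- (img / 255 - 0.5) / 0.5
  }
  list(x = x, labels = as.character(manifest$class))
}

#' @export
print.vgg_network <- function(x, ...) {
  wi <- weight_layer_indices(x)
  cat(sprintf("VGG-19-style network: %d weight layers, %d classes, input %dx%d, scale 1/%d\n",
              length(wi), x$num_classes, x$input_size, x$input_size,
              x$scale_factor))
  blocks <- vapply(x$layers[wi], function(l) l$block, character(1))
  train <- vapply(x$layers[wi], function(l) isTRUE(l$trainable), logical(1))
  for (b in paste0("B", 1:6)) {
    sel <- blocks == b
    cat(sprintf("  %s: %d weight layers [%s]\n", b, sum(sel),
                if (all(train[sel])) "trainable" else
                  if (any(train[sel])) "mixed" else "frozen"))
  }
  cat("trainable parameters:", count_trainable_params(x), "\n")
  invisible(x)
}

#' @export
print.vgg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %d epochs; final loss %.4f, train accuracy %.1f%%",
              nrow(h), h$loss[nrow(h)], h$train_accuracy[nrow(h)]))
  if (!is.na(h$test_accuracy[nrow(h)]))
    cat(sprintf(", test accuracy %.1f%%", h$test_accuracy[nrow(h)]))
  cat("\n")
  invisible(x)
}

#' @export
plot.vgg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  invisible(x)
}
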
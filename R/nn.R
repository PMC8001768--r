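# Minimal CNN engine. Batches are channels-first (C, H, W, N) arrays
# internally; the public array convention is (H, W, C, N) and nn_forward
# converts once at entry. The 3x3 same-padding convolution and 2x2
# max-pooling kernels are compiled (src/nn_ops.cpp: im2col + BLAS through
# Armadillo); ReLU, inverted dropout, fully connected layers and softmax
# cross-entropy complete the vocabulary. Training is SGD + momentum +
# weight decay; everything is seeded and deterministic on a fixed BLAS.

softmax_probs <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

# Forward pass. `x` in the public (H, W, C, N) convention. Returns logits
# and a per-layer cache for backprop and activation extraction.
nn_forward <- function(net, x, training = FALSE) {
  cache <- vector("list", length(net$layers))
  cur <- aperm(x, c(3, 1, 2, 4))     # to channels-first
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      cache[[i]] <- list(x = cur, xdim = dim(cur))
      cur <- cpp_conv_fwd(cur, dim(cur), ly$W, ly$b)
    } else if (ly$type == "relu") {
      cache[[i]] <- list(pos = cur > 0)
      cur <- pmax(cur, 0)
    } else if (ly$type == "pool") {
      pf <- cpp_pool_fwd(cur, dim(cur))
      cache[[i]] <- list(xdim = dim(cur), which = pf$which)
      cur <- pf$out
    } else if (ly$type == "flatten") {
      cache[[i]] <- list(xdim = dim(cur))
      d <- dim(cur)
      cur <- matrix(cur, prod(d[1:3]), d[4])
    } else if (ly$type == "fc") {
      cache[[i]] <- list(x = cur)
      cur <- ly$W %*% cur + ly$b
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- array((stats::runif(length(cur)) >= ly$p) / (1 - ly$p),
                      dim = dim(cur))
        cache[[i]] <- list(mask = mask)
        cur <- cur * mask
      } else {
        cache[[i]] <- list(mask = NULL)
      }
    }
    cache[[i]]$out <- if (ly$type %in% c("relu", "fc")) cur else NULL
  }
  list(logits = cur, cache = cache)
}

# Backward pass from d(loss)/d(logits). Parameter gradients are computed
# for trainable weight layers only, and propagation stops below the deepest
# layer that still needs a gradient (unless `record_dact`, used by the
# class-activation mapping, which keeps every intermediate gradient).
nn_backward <- function(net, cache, dlogits, record_dact = FALSE) {
  grads <- vector("list", length(net$layers))
  dacts <- if (record_dact) vector("list", length(net$layers)) else NULL
  trainables <- which(vapply(net$layers, function(l)
    l$type %in% c("conv", "fc") && isTRUE(l$trainable), logical(1)))
  stop_at <- if (record_dact || length(trainables) == 0) 1L else min(trainables)
  dcur <- dlogits
  for (i in rev(seq_along(net$layers))) {
    if (i < stop_at) break
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "conv") {
      need_gw <- isTRUE(ly$trainable)
      need_dx <- record_dact || i > stop_at
      cb <- cpp_conv_bwd(dcur, cc$x, cc$xdim, ly$W, need_gw, need_dx)
      if (need_gw) grads[[i]] <- list(gW = cb$gW, gb = cb$gb)
      dcur <- if (need_dx) cb$dx else NULL
    } else if (ly$type == "relu") {
      dcur <- dcur * cc$pos
    } else if (ly$type == "pool") {
      dcur <- cpp_pool_bwd(dcur, cc$which, cc$xdim)
    } else if (ly$type == "flatten") {
      dcur <- array(dcur, cc$xdim)
    } else if (ly$type == "fc") {
      if (isTRUE(ly$trainable))
        grads[[i]] <- list(gW = tcrossprod(dcur, cc$x), gb = rowSums(dcur))
      dcur <- crossprod(ly$W, dcur)
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) dcur <- dcur * cc$mask
    }
    if (record_dact) dacts[[i]] <- dcur
  }
  list(grads = grads, dacts = dacts)
}
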
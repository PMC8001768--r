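mini_net <- function(num_classes = 2, seed = 1, input = 32, scale = 8) {
  build_network(num_classes, scale_factor = scale, input_size = input,
                seed = seed)
}

test_that("network structure: 19 weight layers, pattern and widths", {
  net <- mini_net(num_classes = 8)
  expect_equal(n_weight_layers(net), 19)
  wi <- histopatch:::weight_layer_indices(net)
  kinds <- vapply(net$layers[wi], `[[`, character(1), "type")
  expect_equal(sum(kinds == "conv"), 16)
  expect_equal(sum(kinds == "fc"), 3)
  blocks <- vapply(net$layers[wi], `[[`, character(1), "block")
  expect_equal(unname(table(blocks)[paste0("B", 1:5)]), c(2, 2, 4, 4, 4),
               ignore_attr = TRUE)
  expect_equal(sum(blocks == "B6"), 3)
  # final layer width = num_classes
  expect_equal(nrow(net$layers[[wi[19]]]$W), 8)
  # miniature scaling divides widths but keeps the pattern
  expect_equal(n_weight_layers(mini_net(scale = 4)), 19)
  # full-width head: penultimate fully connected layer is 4096 wide
  full <- build_network(2, scale_factor = 1, input_size = 32, seed = 1)
  expect_equal(nrow(full$layers[[histopatch:::weight_layer_indices(full)[18]]]$W),
               4096)
  expect_error(build_network(1), "num_classes")
  expect_error(build_network(2, scale_factor = 0), "scale_factor")
  expect_error(build_network(2, input_size = 50), "divisible")
})

test_that("block-wise schedules freeze the right layers and grow monotonically", {
  net <- mini_net()
  n6 <- apply_blockwise_schedule(net, "B6")
  wi <- histopatch:::weight_layer_indices(n6)
  train6 <- vapply(n6$layers[wi], function(l) isTRUE(l$trainable), logical(1))
  expect_equal(sum(train6), 3)          # only the dense head
  n1 <- apply_blockwise_schedule(net, "B1")
  expect_true(all(vapply(n1$layers[wi], function(l) isTRUE(l$trainable),
                         logical(1))))  # full fine-tuning
  n3 <- apply_blockwise_schedule(net, "B3")
  kinds <- vapply(n3$layers[wi], `[[`, character(1), "type")
  train3 <- vapply(n3$layers[wi], function(l) isTRUE(l$trainable), logical(1))
  expect_equal(sum(train3 & kinds == "conv"), 12)   # B3+B4+B5 = 4+4+4
  expect_equal(sum(!train3 & kinds == "conv"), 4)   # B1+B2 frozen
  # strictly increasing trainable-parameter counts B6 -> B1
  counts <- vapply(paste0("B", 6:1), function(b)
    count_trainable_params(apply_blockwise_schedule(net, b)), numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(apply_blockwise_schedule(net, "B7"), "B1")
})

test_that("augmentations preserve pixel multisets and compose as expected", {
  set.seed(2)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # rot180 twice is the identity
  expect_equal(augment_image(augment_image(img, 5), 5), img)
  # h-flip preserves the pixel multiset exactly
  expect_equal(sort(as.vector(augment_image(img, 2))), sort(as.vector(img)))
  for (tr in 1:6)
    expect_equal(sort(as.vector(augment_image(img, tr))),
                 sort(as.vector(img)))
  # rot90 followed by rot270 is the identity
  expect_equal(augment_image(augment_image(img, 4), 6), img)
  expect_error(augment_image(array(0, c(4, 6, 3)), 4), "square")
})

test_that("the six augmentations are drawn uniformly", {
  set.seed(31)
  img <- array(runif(12), c(2, 2, 3))
  variants <- lapply(1:6, function(tr) augment_image(img, tr))
  expect_equal(length(unique(lapply(variants, as.vector))), 6)
  draws <- replicate(6000, {
    out <- augment_image(img)
    which(vapply(variants, identical, logical(1), out))
  })
  freq <- tabulate(draws, 6) / 6000
  expect_true(all(abs(freq - 1 / 6) < 0.02))
})

test_that("training learns separable data, decreases loss and freezes blocks", {
  ds <- make_tiny_dataset(n_per_class = 80, size = c(32, 32), seed = 5)
  loaded <- load_manifest_images(ds$manifest, ds$dir, size = 32)
  net <- mini_net(seed = 3)
  net <- apply_blockwise_schedule(net, "B3")
  wi <- histopatch:::weight_layer_indices(net)
  frozen <- wi[vapply(net$layers[wi], function(l) !isTRUE(l$trainable),
                      logical(1))]
  before <- lapply(net$layers[frozen], `[[`, "W")
  fit <- train_network(net, loaded$x, loaded$labels,
                       train_config(epochs = 12, seed = 7))
  expect_equal(nrow(fit$history), 12)
  # loss decreases over the epochs of a learnable problem
  expect_lt(fit$history$loss[12], fit$history$loss[1])
  expect_gte(utils::tail(fit$history$train_accuracy, 1), 80)
  # freeze contract: frozen parameters bit-identical after training
  after <- lapply(fit$net$layers[frozen], `[[`, "W")
  expect_identical(before, after)
  expect_equal(sum(vapply(seq_along(before), function(i)
    sum(abs(before[[i]] - after[[i]])), numeric(1))), 0)
})

test_that("training is deterministic for a fixed seed", {
  ds <- make_tiny_dataset(n_per_class = 16, size = c(32, 32), seed = 9)
  loaded <- load_manifest_images(ds$manifest, ds$dir, size = 32)
  f1 <- train_network(mini_net(seed = 2), loaded$x, loaded$labels,
                      train_config(epochs = 3, seed = 11))
  f2 <- train_network(mini_net(seed = 2), loaded$x, loaded$labels,
                      train_config(epochs = 3, seed = 11))
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$net$layers, f2$net$layers)
})

test_that("deep features come from the penultimate rectified layer", {
  net <- mini_net(seed = 4)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  x[, , , 2] <- x[, , , 1]            # two identical images
  feats <- extract_deep_features(net, x)
  expect_equal(dim(feats), c(3, 512)) # 4096 / scale 8
  expect_true(all(feats >= 0))        # post-rectifier
  expect_equal(feats[1, ], feats[2, ])
  full <- build_network(2, scale_factor = 1, input_size = 32, seed = 1)
  f1 <- extract_deep_features(full, x[, , , 1, drop = FALSE])
  expect_equal(ncol(f1), 4096)
  expect_error(extract_deep_features(net, array(0, c(64, 64, 3, 1))),
               "input size")
})
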
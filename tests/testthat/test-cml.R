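make_blobs <- function(n_per = 50, p = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

test_that("classifier specs carry the study defaults and survive JSON", {
  expect_equal(classifier_spec("knn")$hyperparameters$k, 3)
  expect_equal(classifier_spec("rf")$hyperparameters$ntree, 100)
  mlp <- classifier_spec("mlp")$hyperparameters
  expect_equal(mlp$hidden, 100)
  expect_equal(mlp$l2, 1e-4)
  expect_equal(mlp$learning_rate, 1e-3)
  expect_equal(mlp$max_iter, 2000)
  ada <- classifier_spec("adaboost")$hyperparameters
  expect_equal(ada$n_estimators, 50)
  expect_equal(ada$learning_rate, 1)
  expect_equal(classifier_spec("svm")$hyperparameters$cost, 5)
  expect_error(classifier_spec("knn", bogus = 1), "unknown")
  sp <- classifier_spec("svm")
  rt <- jsonlite::fromJSON(jsonlite::toJSON(unclass(sp), auto_unbox = TRUE))
  expect_equal(rt$hyperparameters$cost, sp$hyperparameters$cost)
  expect_equal(rt$kind, sp$kind)
})

test_that("stratified folds partition, balance and reproduce", {
  y <- rep(c("a", "b"), each = 50)
  f <- make_folds(y, k = 10, seed = 1)
  tests <- lapply(f$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 10))
  for (fd in f$folds) {
    expect_equal(sum(y[fd$test] == "a"), 5)
    expect_length(intersect(fd$test, c(fd$train, fd$validation)), 0)
    expect_length(intersect(fd$train, fd$validation), 0)
    # validation is 30% of the training portion, stratified per class
    rest <- c(fd$train, fd$validation)
    for (cl in c("a", "b")) {
      expect_equal(sum(y[fd$validation] == cl),
                   round(0.3 * sum(y[rest] == cl)))
    }
  }
  expect_identical(make_folds(y, k = 10, seed = 1)$folds, f$folds)
  expect_error(make_folds(rep(c("a", "b"), c(5, 95)), k = 10), "a")
})

test_that("fold invariants hold across a 20-seed sweep", {
  set.seed(42)
  y <- sample(rep(c("a", "b", "c"), c(37, 23, 40)))
  for (s in 1:20) {
    f <- make_folds(y, k = 10, seed = s)
    tests <- lapply(f$folds, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_along(y))
    sizes <- lengths(tests)
    expect_lte(diff(range(sizes)), 1)
    # stratification within one record of the global proportion
    for (cl in c("a", "b", "c")) {
      per_fold <- vapply(tests, function(t) sum(y[t] == cl), numeric(1))
      expect_lte(diff(range(per_fold)), 1)
    }
  }
})

test_that("metrics arithmetic matches hand-computed confusion matrices", {
  perfect <- compute_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$precision, 100)

  # confusion [[8,2],[4,6]] by construction
  y_true <- rep(c("a", "b"), c(10, 10))
  y_pred <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(unname(m$confusion["a", ]), c(8, 2), ignore_attr = TRUE)
  expect_equal(unname(m$confusion["b", ]), c(4, 6), ignore_attr = TRUE)
  expect_equal(m$accuracy, 70)
  expect_equal(m$recall, 70)
  expect_equal(m$precision, (8 / 12 + 6 / 8) / 2 * 100, tolerance = 1e-10)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion) * 100)

  # all-one-class predictor on balanced binary: macro recall 50
  m2 <- compute_metrics(rep(c("a", "b"), 10), rep("a", 20),
                        class_set = c("a", "b"))
  expect_equal(m2$recall, 50)
  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics("a", c("a", "b")), "length")
})

test_that("every classifier separates distant Gaussian blobs perfectly", {
  blobs <- make_blobs(n_per = 100, sep = 10, seed = 3)
  folds <- make_folds(blobs$y, k = 10, seed = 2)
  for (kind in c("knn", "rf", "mlp", "svm")) {
    rep <- train_eval(blobs$x, blobs$y, classifier_spec(kind), folds, seed = 4)
    expect_equal(rep$accuracy, 100, info = kind)
    expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion) * 100)
  }
  # adaboost with few rounds is enough on separable data
  rep <- train_eval(blobs$x, blobs$y,
                    classifier_spec("adaboost", n_estimators = 10),
                    folds, seed = 4)
  expect_gte(rep$accuracy, 99)
})

test_that("permuted labels score inside the binomial null band", {
  set.seed(8)
  x <- matrix(rnorm(500 * 5), 500, 5)
  y <- sample(rep(c("a", "b"), 250))   # labels independent of features
  folds <- make_folds(y, k = 10, seed = 1)
  rep <- train_eval(x, y, classifier_spec("knn"), folds, seed = 2)
  expect_gt(rep$accuracy, 43)   # 50 +/- 7, binomial 99% band at n = 500
  expect_lt(rep$accuracy, 57)
})

test_that("knn prediction matches exhaustive neighbour enumeration with deterministic ties", {
  # 4 hand-listed 2-D points; test point equidistant to the two classes
  xtr <- rbind(c(0, 1), c(0, -1), c(2, 1), c(2, -1))
  ytr <- c("a", "a", "b", "b")
  model <- histopatch:::knn_fit(xtr, ytr, classifier_spec("knn"))
  # (1, 0): neighbours at distance sqrt(2) all four; order() keeps the first
  # three training indices -> votes a, a, b -> "a"
  expect_equal(histopatch:::knn_predict(model, rbind(c(1, 0))), "a")
  # exhaustive check against brute-force 3-NN on random data
  set.seed(10)
  xtr <- matrix(rnorm(40), 20, 2); ytr <- rep(c("a", "b"), 10)
  xte <- matrix(rnorm(10), 5, 2)
  model <- histopatch:::knn_fit(xtr, ytr, classifier_spec("knn"))
  pred <- histopatch:::knn_predict(model, xte)
  for (i in 1:5) {
    d <- sqrt(colSums((t(xtr) - xte[i, ])^2))
    nn <- order(d)[1:3]
    tab <- table(factor(ytr[nn], levels = c("a", "b")))
    expect_equal(pred[i], names(tab)[which.max(tab)])
  }
})

test_that("non-finite features are rejected with row information", {
  blobs <- make_blobs(n_per = 20, seed = 5)
  blobs$x[7, 2] <- NA
  folds <- make_folds(blobs$y, k = 4, seed = 1)
  expect_error(train_eval(blobs$x, blobs$y, classifier_spec("knn"), folds),
               "7")
})

test_that("rf accuracy rises with the class-separation knob", {
  # monotone signal property on the synthetic generator: widen the
  # morphology gap across three settings and track CV accuracy
  gaps <- list(c(3.2, 4.4), c(3.8, 5.8), c(5, 9))
  accs <- numeric(3)
  for (gi in seq_along(gaps)) {
    specs <- list(
      benign = class_spec("benign", nucleus_radius_range = c(2.5, 4),
                          margin_irregularity = 0.05),
      malignant = class_spec("malignant",
                             nucleus_radius_range = gaps[[gi]],
                             margin_irregularity = 0.05 + 0.1 * gi))
    dir <- tempfile()
    man <- generate_dataset(data.frame(class = c("benign", "malignant"),
                                       n = 40),
                            dir, seed = 6, specs = specs, size = c(32, 32))
    tab <- extract_features(man, dir, resize_to = NULL)
    folds <- make_folds(tab$class, k = 5, seed = 2)
    rep <- train_eval(as.matrix(tab[, 1:550]), tab$class,
                      classifier_spec("rf"), folds, seed = 3)
    accs[gi] <- rep$accuracy
  }
  expect_true(all(diff(accs) >= 0))
})
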
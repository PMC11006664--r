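identity_scaling <- list(mean = rep(0, 4), sd = rep(1, 4))

test_that("train/validation split is exhaustive, disjoint and seeded", {
  tab <- toy_table(10)
  parts <- split_train_validation(tab, 0.8, seed = 1)
  expect_identical(nrow(parts$train), 8L)
  expect_identical(nrow(parts$validation), 2L)
  expect_setequal(c(parts$train$row, parts$validation$row), tab$row)
  parts2 <- split_train_validation(tab, 0.8, seed = 1)
  expect_identical(parts$train$row, parts2$train$row)
  big <- toy_table(1000)
  p <- split_train_validation(big, 0.8, seed = 3)
  expect_length(intersect(p$train$row, p$validation$row), 0L)
  unlab <- big; unlab$label <- NULL
  expect_error(split_train_validation(unlab, 0.8, 1), "missing-labels")
})

test_that("forward pass reproduces hand-evaluated affine/ReLU/sigmoid cases", {
  # no hidden layer, all-zero weights: sigmoid(0) = 0.5 for any input
  m0 <- posimap:::new_model(c(4L, 1L), list(matrix(0, 4, 1)), list(0),
                            identity_scaling)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, c("blue", "green", "red", "depth")))
  expect_equal(forward(m0, X), rep(0.5, 5))
  # single passthrough weight: sigmoid(1) on the unit input
  m1 <- posimap:::new_model(c(4L, 1L), list(matrix(c(1, 0, 0, 0), 4, 1)),
                            list(0), identity_scaling)
  expect_equal(forward(m1, matrix(c(1, 0, 0, 0), 1, 4)),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(forward(m1, matrix(c(1, 0, 0, 0), 1, 4)), 0.7310586,
               tolerance = 1e-7)
  # negative pre-activation is rectified to zero: output is sigmoid(b_out)
  # regardless of the downstream weight
  mh <- posimap:::new_model(
    c(4L, 1L, 1L),
    list(matrix(c(1, 0, 0, 0), 4, 1), matrix(5, 1, 1)),
    list(-2, 0.3), identity_scaling)
  p <- forward(mh, matrix(c(0, 0, 0, 0), 1, 4))  # pre-activation -2 -> ReLU 0
  expect_equal(p, 1 / (1 + exp(-0.3)), tolerance = 1e-12)
  expect_error(forward(m1, matrix(0, 2, 3)), "shape error")
})

test_that("forward pass matches the per-row loop oracle on random models", {
  for (seed in 1:10) {
    m <- random_tiny_model(seed)
    X <- withr::with_seed(seed + 100, matrix(rnorm(40), 10, 4))
    colnames(X) <- c("blue", "green", "red", "depth")
    expect_equal(forward(m, X), forward_oracle(m, X), tolerance = 1e-10)
    p <- forward(m, X)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("training learns a separable rule, deterministically", {
  tab <- toy_table(1000)
  cfg <- training_config(batch_size = 64, epochs = 200, learning_rate = 0.1,
                         seed = 11)
  fit <- train_classifier(tab, c(16L, 8L), cfg)
  pred <- classify(fit$model, forward(fit$model, tab))
  expect_gte(mean(pred == tab$label), 0.99)
  # loss trends downward
  h <- fit$history$train_loss
  expect_lt(mean(utils::tail(h, 10)), mean(utils::head(h, 10)))
  # same seed twice: identical weights
  fit2 <- train_classifier(tab, c(16L, 8L), cfg)
  expect_identical(fit$model$weights, fit2$model$weights)
  # different seed: different initialization and different weights
  fit3 <- train_classifier(tab, c(16L, 8L),
                           training_config(batch_size = 64, epochs = 200,
                                           learning_rate = 0.1, seed = 12))
  expect_false(identical(fit$model$weights, fit3$model$weights))
  ones <- tab; ones$label <- 1L
  expect_error(train_classifier(ones, c(4L), cfg), "degenerate-labels")
})

test_that("training is invariant to the caller's row order", {
  tab <- toy_table(400)
  cfg <- training_config(batch_size = 64, epochs = 30, seed = 2)
  fit_a <- train_classifier(tab, c(8L), cfg)
  shuffled <- withr::with_seed(99, tab[sample.int(nrow(tab)), ])
  fit_b <- train_classifier(shuffled, c(8L), cfg)
  expect_identical(fit_a$model$weights, fit_b$model$weights)
})

test_that("classification thresholds probabilities with the documented tie rule", {
  m <- posimap:::new_model(c(4L, 1L), list(matrix(0, 4, 1)), list(0),
                           identity_scaling)
  expect_identical(classify(m, c(0.2, 0.49, 0.5, 0.51, 0.8)),
                   c(0L, 0L, 1L, 1L, 1L))
})

test_that("predicted maps write classes back by pixel index", {
  comp <- raster_grid(array(runif(48), c(4, 4, 3)), 10,
                      band_names = c("blue", "green", "red"))
  bathy <- flat_bathy(4, 4, 15)
  tab <- build_feature_table(comp, bathy)
  m0 <- posimap:::new_model(c(4L, 1L), list(matrix(0, 4, 1)), list(0),
                            attr(tab, "scaling"))
  pred <- predict_map(m0, tab, comp)
  # all-zero weights give probability 0.5 everywhere; the tie maps to PO
  expect_true(all(pred$values[pred$mask] == 1))
  # round-trip: reading back by index reproduces the class vector
  cls <- classify(m0, forward(m0, tab))
  expect_identical(pred$values[, , 1][cbind(tab$row, tab$col)], as.numeric(cls))
  # empty table gives an all-invalid raster of the target shape
  empty <- tab[0, , drop = FALSE]
  pe <- predict_map(m0, empty, comp)
  expect_false(any(pe$mask))
  bad <- tab; bad$row[1] <- 99L
  expect_error(predict_map(m0, bad, comp), "integrity error")
})

test_that("models survive a save/load round trip bit-identically", {
  tab <- toy_table(300)
  fit <- train_classifier(tab, c(8L, 4L),
                          training_config(epochs = 20, seed = 4))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, tmp)
  m2 <- load_model(tmp)
  X <- withr::with_seed(5, matrix(runif(400), 100, 4))
  colnames(X) <- c("blue", "green", "red", "depth")
  expect_identical(forward(m2, X), forward(fit$model, X))
  expect_identical(m2$layer_sizes, fit$model$layer_sizes)
  # different seeds write different files
  fit_b <- train_classifier(tab, c(8L, 4L),
                            training_config(epochs = 20, seed = 5))
  tmp_b <- withr::local_tempfile(fileext = ".json")
  save_model(fit_b$model, tmp_b)
  expect_false(identical(readLines(tmp), readLines(tmp_b)))
  # corruption is a format error, not silent garbage
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(tmp), collapse = ""), 1, 80), bad)
  expect_error(load_model(bad), "format error")
  writeLines('{"format": "posimap-dlnn", "version": 1}', bad)
  expect_error(load_model(bad), "format error")
})
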
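test_that("pearson_correlation matches direct evaluation and is symmetric", {
  v <- c(2, 4, 1, 7)
  expect_equal(pearson_correlation(v, v), 1.0)
  expect_equal(pearson_correlation(v, -v), -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_correlation(c(1, 3, 2, 4), c(1, 2, 3, 4)), 0.8)
  expect_error(pearson_correlation(rep(1, 4), v), "constant")
  expect_error(pearson_correlation(1:3, 1:4), "length")
  expect_error(pearson_correlation(1, 1), "2 samples")
})

test_that("noise injection is reproducible, unbiased and inert at sd 0", {
  pred <- matrix(rnorm(20), 4, 5)
  expect_identical(inject_noise(pred, 0), pred)
  set.seed(9); a <- inject_noise(pred, 1)
  set.seed(9); b <- inject_noise(pred, 1)
  expect_identical(a, b)
  expect_error(inject_noise(pred, -1), ">= 0")
  # moment check at a million draws
  set.seed(10)
  big <- inject_noise(matrix(0, 1000, 1000), 1)
  expect_lt(abs(mean(big)), 0.005)
  expect_true(abs(sd(big) - 1) < 0.005)
})

test_that("encoding loss reaches -1 exactly at perfect zero-mean prediction", {
  set.seed(11)
  actual <- matrix(rnorm(40), 8, 5)
  pred <- scale(actual, scale = FALSE) # identical up to centring: rho = 1
  expect_equal(encoding_loss(pred, actual, gamma = 5), -1.0)
  expect_gte(encoding_loss(matrix(rnorm(40), 8, 5), actual, 0), -1)
})

test_that("cubed correlations cancel for opposite-sign voxel pairs", {
  x <- scale(rnorm(10), scale = FALSE)[, 1]
  pred <- cbind(x, -x)
  actual <- cbind(x, x)
  expect_equal(encoding_loss(pred, actual, gamma = 0), 0)
})

test_that("with zero correlation the loss reduces to the mean-magnitude penalty", {
  # prediction orthogonal to the actual response, constant mean c
  actual <- matrix(c(1, -1, 1, -1), 4, 1)
  pred <- matrix(c(1, 1, -1, -1) + 3, 4, 1)
  expect_equal(encoding_loss(pred, actual, gamma = 2), 2 * 3)
})

test_that("constant prediction columns contribute rho = 0 with a warning", {
  actual <- matrix(rnorm(8), 4, 2)
  pred <- cbind(scale(actual[, 1], scale = FALSE), rep(0, 4))
  expect_warning(l <- encoding_loss(pred, actual, gamma = 0), "constant")
  expect_equal(l, -0.5)
})

test_that("the loss gradient on raw fc weights carries the 2w chain factor", {
  m <- random_tiny_model(51)
  x <- tiny_stimuli(6, seed = 52)
  set.seed(53)
  actual <- matrix(rnorm(18), 6, 3)
  fwd <- gaborenc:::forward_cached(m, x)
  lg <- gaborenc:::correlation_loss_grad(fwd$pred, actual, gamma = 0.5)
  gr <- gaborenc:::model_gradients(m, fwd, lg$grad)
  eff_grad <- fwd$f %*% lg$grad          # gradient w.r.t. effective weights
  expect_equal(gr$fc_w, 2 * m$fc_w * eff_grad, tolerance = 1e-12)
  # spot finite-difference check across parameter groups
  pars <- gaborenc:::model_parameters(m)
  h <- 1e-5
  for (nm in c("gabor_omega", "gabor_sigma", "conv1_w", "fc_w")) {
    i <- 1L
    pp <- pars; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- pars; pm[[nm]][i] <- pm[[nm]][i] - h
    lp <- encoding_loss(forward_pass(gaborenc:::set_model_parameters(m, pp), x), actual, 0.5)
    lm <- encoding_loss(forward_pass(gaborenc:::set_model_parameters(m, pm), x), actual, 0.5)
    fd <- (lp - lm) / (2 * h)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-5 + abs(fd) * 1e-3)
  }
})

test_that("cross-validation folds partition the indices into near-equal parts", {
  folds <- cv_folds(10, 5, seed = 1)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), 1:10)
  folds2 <- cv_folds(11, 3, seed = 2)
  expect_setequal(unlist(folds2), 1:11)
  expect_lte(diff(range(lengths(folds2))), 1)
  expect_identical(cv_folds(10, 5, seed = 4), cv_folds(10, 5, seed = 4))
  expect_error(cv_folds(10, 1), "k")
  expect_error(cv_folds(3, 5), "n_samples")
})

test_that("training is deterministic and reduces the loss on a small task", {
  ds <- synthetic_dataset(n_train = 64, n_val = 16, side = 16, n_voxels = 4,
                          seed = 61)
  cfg <- model_config(input_size = 16, n_voxels = 4, kernels_per_branch = 8,
                      conv_filters = 16L)
  tc <- training_config(batch_size = 32, epochs = 25, seed = 62, gamma = 0,
                        noise_sd = 0.5)
  r1 <- fit_encoding_model(build_model(cfg, seed = 60), ds$train_stimuli,
                           ds$train_responses, tc)
  r2 <- fit_encoding_model(build_model(cfg, seed = 60), ds$train_stimuli,
                           ds$train_responses, tc)
  expect_identical(gaborenc:::model_parameters(r1$model),
                   gaborenc:::model_parameters(r2$model))
  expect_equal(nrow(r1$history), 25)
  # trend check on epoch medians: the second half improves on the first
  first <- median(r1$history$loss[1:12])
  second <- median(r1$history$loss[13:25])
  expect_lt(second, first)
})

test_that("the mean-magnitude penalty shrinks the prediction mean", {
  ds <- synthetic_dataset(n_train = 64, n_val = 16, side = 16, n_voxels = 4,
                          seed = 71)
  cfg <- model_config(input_size = 16, n_voxels = 4, kernels_per_branch = 8,
                      conv_filters = 16L)
  tc0 <- training_config(batch_size = 32, epochs = 10, seed = 72, gamma = 0)
  tc10 <- training_config(batch_size = 32, epochs = 10, seed = 72, gamma = 10)
  m0 <- fit_encoding_model(build_model(cfg, seed = 70), ds$train_stimuli,
                           ds$train_responses, tc0)$model
  m10 <- suppressWarnings(
    fit_encoding_model(build_model(cfg, seed = 70), ds$train_stimuli,
                       ds$train_responses, tc10)$model)
  expect_lt(abs(mean(forward_pass(m10, ds$train_stimuli))),
            abs(mean(forward_pass(m0, ds$train_stimuli))))
})

test_that("training rejects inconsistent shapes and invalid settings", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 1)
  x <- tiny_stimuli(4, seed = 1)
  expect_error(fit_encoding_model(m, x, matrix(0, 3, 3), training_config()),
               "rows")
  expect_error(fit_encoding_model(m, x, matrix(0, 4, 2), training_config()),
               "columns")
  expect_error(training_config(batch_size = 1), "batch_size")
  expect_error(training_config(gamma = -1), "non-negative")
})
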
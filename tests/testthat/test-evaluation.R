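test_that("accurate_fraction reproduces the reported area percentages", {
  # counts over totals as reported per visual area
  expect_equal(accurate_fraction(c(rep(0.5, 548), rep(0.1, 1294 - 548)), 0.27)$percentage,
               42.35)
  expect_equal(accurate_fraction(c(rep(0.5, 688), rep(0.1, 2083 - 688)), 0.27)$percentage,
               33.03)
  expect_equal(accurate_fraction(c(rep(0.5, 108), rep(0.1, 928 - 108)), 0.27)$percentage,
               11.64)
  expect_equal(accurate_fraction(numeric(5), 0.27),
               list(count = 0L, percentage = 0, n_voxels = 5L))
})

test_that("exceedance is strict and NAs never count", {
  expect_equal(accurate_fraction(c(0.27, 0.28, NA), 0.27)$count, 1L)
})

test_that("rank_voxels sorts above-threshold voxels, ties by index", {
  r <- rank_voxels(c(0.9, 0.1, 0.5), 0.27)
  expect_equal(r$voxel, c(1, 3))
  expect_equal(r$rho, c(0.9, 0.5))
  expect_equal(nrow(rank_voxels(c(0.1, 0.2), 0.27)), 0)
  set.seed(1)
  rho <- round(runif(50), 1)
  rr <- rank_voxels(rho, 0.2)
  expect_true(all(diff(rr$rho) <= 0))
  ties <- split(rr$voxel, rr$rho)
  expect_true(all(vapply(ties, function(v) all(diff(v) > 0), logical(1))))
})

test_that("the permutation threshold is near the analytic t-quantile null", {
  set.seed(2)
  actual <- matrix(rnorm(120 * 200), 120, 200)
  predicted <- matrix(rnorm(120 * 200), 120, 200)
  thr <- permutation_threshold(actual, predicted, n_perm = 1000, alpha = 0.001,
                               seed = 3)
  expect_lt(abs(thr - gaborenc:::analytic_null_quantile(120, 0.001)), 0.02)
  # alpha = 0.5 sits at the symmetric null median
  thr50 <- permutation_threshold(actual, predicted, n_perm = 100, alpha = 0.5,
                                 seed = 4)
  expect_lt(abs(thr50), 0.02)
})

test_that("the permutation threshold is monotone non-increasing in alpha", {
  set.seed(5)
  actual <- matrix(rnorm(60 * 50), 60, 50)
  predicted <- matrix(rnorm(60 * 50), 60, 50)
  alphas <- c(0.001, 0.01, 0.05, 0.25)
  thrs <- vapply(alphas, function(a) {
    permutation_threshold(actual, predicted, n_perm = 1000, alpha = a, seed = 6)
  }, numeric(1))
  expect_true(all(diff(thrs) <= 0))
  expect_error(permutation_threshold(actual, predicted, alpha = 0), "alpha")
  expect_error(permutation_threshold(actual, predicted, n_perm = 100,
                                     alpha = 0.001), "n_perm")
})

test_that("under the global null the exceedance rate matches alpha", {
  set.seed(7)
  n_vox <- 400
  actual <- matrix(rnorm(60 * n_vox), 60, n_vox)
  predicted <- matrix(rnorm(60 * n_vox), 60, n_vox)
  thr <- permutation_threshold(actual, predicted, n_perm = 1000, alpha = 0.01,
                               seed = 8)
  hits <- sum(gaborenc:::colwise_pearson(predicted, actual) > thr)
  # binomial(400, 0.01): accept within +/- 4 sd
  expect_lt(abs(hits - 4), 4 * sqrt(400 * 0.01 * 0.99) + 1)
})

test_that("voxelwise accuracy is perfect for a model predicting the data", {
  ds <- synthetic_dataset(n_train = 40, n_val = 24, seed = 9)
  m <- wire_ground_truth_model(ds$voxels, side = 32)
  vr <- apply(ds$val_responses, c(2, 3), mean)
  rep <- voxelwise_accuracy(m, ds$val_stimuli, vr, threshold = 0.27)
  expect_equal(unname(rep$rho), rep(1, 20), tolerance = 1e-10)
  expect_equal(rep$count, 20L)
  expect_equal(rep$percentage, 100)
  expect_equal(rep$ranking$voxel[order(rep$ranking$voxel)], 1:20)
})

test_that("repeat dimensions are averaged and constant voxels excluded", {
  ds <- synthetic_dataset(n_train = 40, n_val = 24, seed = 10, noise_sd = 0.5)
  m <- wire_ground_truth_model(ds$voxels, side = 32)
  rep3d <- voxelwise_accuracy(m, ds$val_stimuli, ds$val_responses,
                              threshold = 0.27)
  vr <- apply(ds$val_responses, c(2, 3), mean)
  rep2d <- voxelwise_accuracy(m, ds$val_stimuli, vr, threshold = 0.27)
  expect_equal(rep3d$rho, rep2d$rho)
  # constant measured column is flagged and dropped from the count
  vr_bad <- vr; vr_bad[, 3] <- 1
  expect_message(repc <- voxelwise_accuracy(m, ds$val_stimuli, vr_bad,
                                            threshold = 0.27), "flagged")
  expect_true(is.na(repc$rho[3]))
  expect_equal(repc$count, 19L)
})

test_that("dominance verdicts follow the fair-coin null", {
  set.seed(11)
  rho <- runif(400, 0.3, 0.9)
  # identical accuracies: fraction near 0.5, not significant
  r_eq <- dominance_test(rho, rho, threshold = 0.27, seed = 12)
  expect_equal(r_eq$n_shared, 400L)
  expect_lt(abs(r_eq$fraction_a - 0.5), 0.1)
  expect_false(r_eq$significant)
  # strict dominance: fraction 1, significant
  r_dom <- dominance_test(rho + 0.01, rho, threshold = 0.27, seed = 13)
  expect_equal(r_dom$fraction_a, 1)
  expect_true(r_dom$significant)
  # empty restricted set: explicit no-test
  r_none <- dominance_test(c(0.1, 0.2), c(0.15, 0.1), threshold = 0.27)
  expect_true(r_none$no_test)
})

test_that("dominance is antisymmetric up to tie randomization", {
  set.seed(14)
  rho_a <- runif(300, 0.3, 0.9)
  rho_b <- rho_a + rnorm(300, 0, 0.05)
  f_ab <- dominance_test(rho_a, rho_b, 0.27, seed = 15)$fraction_a
  f_ba <- dominance_test(rho_b, rho_a, 0.27, seed = 15)$fraction_a
  expect_equal(f_ab, 1 - f_ba, tolerance = 1e-12)
})

test_that("accuracy reports round-trip through CSV and JSON", {
  ds <- synthetic_dataset(n_train = 40, n_val = 24, seed = 16)
  m <- wire_ground_truth_model(ds$voxels, side = 32)
  rep <- voxelwise_accuracy(m, ds$val_stimuli,
                            apply(ds$val_responses, c(2, 3), mean),
                            threshold = 0.27, roi = "V1")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_accuracy_report(rep, csv, js)
  df <- read.csv(csv)
  expect_equal(nrow(df), 20)
  expect_equal(sum(df$accurate), rep$count)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$percentage, 100)
  expect_equal(summ$roi, "V1")
})
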
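fake_loocv <- function(ids, ages, preds) {
  structure(data.frame(sample_id = ids, dental_age = ages,
                       predicted_age = preds, residual = preds - ages,
                       abs_error = abs(preds - ages), stringsAsFactors = FALSE),
            class = c("loocv_result", "data.frame"))
}

test_that("subset rules reproduce the relaxed/strict/restricted arithmetic", {
  n <- 75
  flags <- rep(FALSE, n); flags[c(10, 20)] <- TRUE
  ds <- toy_dataset(n = n, p = 4, seed = 70, ages = seq(0, 34, length.out = n),
                    min_age_flags = flags)
  err <- rep(1, n); err[seq(3, 69, by = 6)] <- 7 # 12 samples above 6 y
  loo <- fake_loocv(ds$sample_ids, ds$samples$dental_age,
                    ds$samples$dental_age + err)
  subs <- build_subsets(ds, loo)
  expect_length(subs$relaxed, 75)
  expect_length(subs$strict, 73)
  expect_length(subs$restricted, 63)
  expect_true(all(subs$strict %in% subs$relaxed))
  expect_true(all(subs$restricted %in% subs$relaxed))

  wide <- build_subsets(ds, loo, error_cutoff = Inf)
  expect_identical(wide$restricted, wide$relaxed)
  expect_error(build_subsets(ds, loo[-1, ]), "lacks")
})

test_that("a sample at exactly the cutoff leaves restricted but is not counted above 6", {
  ds <- toy_dataset(n = 5, p = 3, seed = 71, ages = c(1, 5, 10, 20, 30))
  preds <- c(1, 5, 16, 20, 30) # one error of exactly 6 years
  loo <- fake_loocv(ds$sample_ids, ds$samples$dental_age, preds)
  subs <- build_subsets(ds, loo)
  expect_false("S03" %in% subs$restricted)
  expect_equal(evaluate_predictions(loo)$n_err_gt6, 0)
})

test_that("the error-metric suite matches hand-computed values", {
  ages <- c(2, 8, 15, 22, 30)
  ev <- suppressWarnings(evaluate_predictions(ages, ages)) # exact fit by design
  expect_equal(ev$mae_median, 0); expect_equal(ev$pearson_r, 1)
  expect_equal(ev$slope, 1); expect_equal(ev$intercept, 0)
  expect_equal(ev$r_squared, 1)

  ev2 <- evaluate_predictions(c(3, 10, 18), c(2, 8, 15))
  expect_equal(ev2$mae_median, 2); expect_equal(ev2$mae_mean, 2)

  ev3 <- evaluate_predictions(c(9, 13, 26), c(2, 8, 15))
  expect_equal(ev3$n_err_gt6, 2); expect_equal(ev3$n_err_gt10, 1)
  expect_equal(ev3$max_abs_error, 11)

  # order invariance
  ord <- c(3, 1, 2)
  expect_equal(unclass(evaluate_predictions(c(9, 13, 26)[ord], c(2, 8, 15)[ord])),
               unclass(ev3))
  expect_error(evaluate_predictions(c(1, 2, 3), c(5, 5, 5)), "variance")
})

test_that("restricting by error never raises the median absolute error", {
  spec <- simulation_spec(n_samples = 30, n_cpgs = 100, n_age_cpgs = 10,
                          n_sex_cpgs = 0, seed = 72)
  ds <- generate_dataset(spec)$dataset
  loo <- loocv_predict(ds, alpha = 0.5, seed = 8)
  subs <- build_subsets(ds, loo, error_cutoff = median(loo$abs_error) * 2)
  keep <- loo$sample_id %in% subs$restricted
  if (sum(keep) >= 3) {
    expect_lte(median(loo$abs_error[keep]), median(loo$abs_error))
  }
})

test_that("the decomposition test reproduces the textbook rank-sum statistic", {
  # hand oracle: H = 12/(n(n+1)) * sum(R_i^2/n_i) - 3(n+1), no ties
  vals <- c(1, 2, 3, 4, 5, 6)
  dcc <- c(1, 1, 1, 2, 2, 2)
  H_hand <- 12 / (6 * 7) * (sum(1:3)^2 / 3 + sum(4:6)^2 / 3) - 3 * 7
  res <- decomposition_effect(vals, dcc)
  expect_equal(res$statistic, H_hand, tolerance = 1e-10)
  expect_equal(res$statistic, 3.857142857, tolerance = 1e-6)
  expect_equal(res$df, 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  # permutation within groups leaves H unchanged
  res2 <- decomposition_effect(c(3, 1, 2, 6, 4, 5), dcc)
  expect_equal(res2$statistic, res$statistic)

  expect_equal(decomposition_effect(rep(2, 6), dcc)$statistic, 0)
  expect_error(decomposition_effect(vals, rep(1, 6)), "categories")
})

test_that("storage effects: perfect monotone, null, and age-confounded cases", {
  mono <- suppressWarnings( # exact monotone fixture saturates the OLS fit
    storage_effect(1:8, 1:8, rep(c(1, 2), 4) + 0.1 * (1:8)))
  expect_equal(mono$spearman$rho, 1)

  set.seed(73)
  n <- 75
  storage <- sample(0:23, n, replace = TRUE)
  err_null <- abs(rnorm(n))
  ages <- runif(n, 0, 34)
  null_res <- storage_effect(err_null, storage, ages)
  expect_lt(abs(null_res$spearman$rho), 0.25)
  ci <- null_res$unadjusted$beta_storage +
    c(-2, 2) * null_res$unadjusted$se_storage
  expect_true(ci[1] < 0 && ci[2] > 0)

  # error driven by age; storage tracks age, so the raw slope is spurious
  set.seed(74)
  ages <- runif(n, 0, 34)
  storage <- ages / 2 + rnorm(n, sd = 2)
  err <- 0.3 * ages + rnorm(n, sd = 0.3)
  conf <- storage_effect(err, storage, ages)
  expect_lt(conf$unadjusted$p_storage, 0.01)       # spurious effect present
  expect_gt(conf$age_adjusted$p_storage, 0.05)     # removed by adjustment
  expect_equal(conf$age_adjusted$beta_age, 0.3, tolerance = 0.1)
  expect_true(abs(conf$age_adjusted$beta_storage) <
                abs(conf$unadjusted$beta_storage))

  expect_error(storage_effect(1:5, rep(3, 5), 1:5), "constant")
})
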
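# Fixture with enough mature animals for the mature-only clock at small n.
hybrid_fixture <- function(n = 24, seed = 50) {
  spec <- simulation_spec(n_samples = n, n_cpgs = 60, n_age_cpgs = 10,
                          n_sex_cpgs = 4, age_skew = 0.8, noise_sd = 0.03,
                          seed = seed)
  generate_dataset(spec)$dataset
}

test_that("maturity labels use inclusive sex-specific thresholds", {
  samples <- data.frame(sex = c("female", "male", "male", "female", "male"),
                        dental_age = c(18, 19, 20, 17.9, 34))
  lab <- label_maturity(samples)
  expect_equal(as.character(lab),
               c("mature", "immature", "mature", "immature", "mature"))
  expect_error(label_maturity(data.frame(sex = "unknown", dental_age = 5)),
               "unknown")
})

test_that("too few mature samples abort the fit with a clear message", {
  spec <- simulation_spec(n_samples = 12, n_cpgs = 30, n_age_cpgs = 6,
                          n_sex_cpgs = 2, age_range = c(0, 10), seed = 51)
  young <- generate_dataset(spec)$dataset
  expect_error(fit_hybrid(young, seed = 1), "mature")
})

test_that("seeded hybrid fits are deterministic", {
  ds <- hybrid_fixture()
  m1 <- fit_hybrid(ds, seed = 7, n_trees = 50, min_mature = 4)
  m2 <- fit_hybrid(ds, seed = 7, n_trees = 50, min_mature = 4)
  p1 <- predict_hybrid(m1, ds)
  p2 <- predict_hybrid(m2, ds)
  expect_identical(p1, p2)
  expect_identical(m1$enr_all$coefficients, m2$enr_all$coefficients)
})

test_that("gate overrides reduce the hybrid to its components", {
  ds <- hybrid_fixture()
  m <- fit_hybrid(ds, seed = 8, n_trees = 50, min_mature = 4)
  p0 <- predict_hybrid(m, ds, gate = 0)
  expect_identical(p0$predicted_age, p0$pred_all)
  p1 <- predict_hybrid(m, ds, gate = 1)
  expect_identical(p1$predicted_age, p1$pred_mature)
  p5 <- predict_hybrid(m, ds, gate = 0.5)
  expect_equal(p5$predicted_age, (p5$pred_all + p5$pred_mature) / 2)
})

test_that("hybrid predictions are convex combinations of the two clocks", {
  ds <- hybrid_fixture(seed = 52)
  m <- fit_hybrid(ds, seed = 9, n_trees = 100, min_mature = 4)
  p <- predict_hybrid(m, ds)
  expect_true(all(p$p_mature >= 0 & p$p_mature <= 1))
  lo <- pmin(p$pred_all, p$pred_mature) - 1e-12
  hi <- pmax(p$pred_all, p$pred_mature) + 1e-12
  expect_true(all(p$predicted_age >= lo & p$predicted_age <= hi))
})

test_that("cross-validation matches a brute-force per-fold refit oracle", {
  ds <- hybrid_fixture()
  k <- 3; seed <- 11
  cv <- cross_validate_hybrid(ds, k = k, seed = seed, n_trees = 50,
                              min_mature = 4)
  labels <- label_maturity(ds$samples)
  folds <- stratified_folds(labels, k, seed)
  oracle <- rep(NA_real_, n_samples(ds))
  for (f in seq_len(k)) {
    train <- subset_samples(ds, ds$sample_ids[folds != f])
    test <- subset_samples(ds, ds$sample_ids[folds == f])
    m <- fit_hybrid(train, seed = derive_seed(seed, paste0("hybrid_fold:", f)),
                    n_trees = 50, min_mature = 4)
    oracle[folds == f] <- predict_hybrid(m, test)$predicted_age
  }
  expect_identical(cv$predicted_age, oracle)

  cv2 <- cross_validate_hybrid(ds, k = k, seed = seed, n_trees = 50,
                               min_mature = 4)
  expect_identical(cv, cv2)
})

test_that("a constant-zero gate makes hybrid CV equal the all-samples clock CV", {
  ds <- hybrid_fixture(seed = 53)
  k <- 3; seed <- 12
  cv0 <- cross_validate_hybrid(ds, k = k, seed = seed, gate = 0, n_trees = 50,
                               min_mature = 4)
  labels <- label_maturity(ds$samples)
  folds <- stratified_folds(labels, k, seed)
  oracle <- rep(NA_real_, n_samples(ds))
  for (f in seq_len(k)) {
    train <- subset_samples(ds, ds$sample_ids[folds != f])
    test <- subset_samples(ds, ds$sample_ids[folds == f])
    m <- fit_hybrid(train, seed = derive_seed(seed, paste0("hybrid_fold:", f)),
                    n_trees = 50, min_mature = 4)
    oracle[folds == f] <- predict_hybrid(m, test)$pred_all
  }
  expect_identical(cv0$predicted_age, oracle)
})

test_that("the maturity forest separates classes on strong-signal data", {
  ds <- generate_dataset(simulation_spec(seed = 54))$dataset
  m <- fit_hybrid(ds, seed = 13, n_trees = 300)
  labels <- label_maturity(ds$samples)
  oob_acc <- mean(m$rfc$predicted == labels)
  expect_gt(oob_acc, 0.9)
})
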
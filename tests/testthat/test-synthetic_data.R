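test_that("identical spec and seed give bit-identical datasets", {
  spec <- simulation_spec(n_samples = 15, n_cpgs = 60, n_age_cpgs = 6,
                          n_sex_cpgs = 3, seed = 9)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$dataset$betas, b$dataset$betas)
  expect_identical(a$dataset$detection_p, b$dataset$detection_p)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(spec, seed = 10)
  expect_false(identical(a$dataset$betas, c$dataset$betas))
})

test_that("betas stay in [0,1] across spec regimes", {
  for (s in list(simulation_spec(n_samples = 10, n_cpgs = 30, noise_sd = 0.5,
                                 n_age_cpgs = 10, n_sex_cpgs = 5, seed = 1),
                 simulation_spec(n_samples = 10, n_cpgs = 30, n_age_cpgs = 20,
                                 n_sex_cpgs = 10, slope_range = c(0.3, 0.6),
                                 seed = 2))) {
    sim <- generate_dataset(s)
    expect_true(all(sim$dataset$betas >= 0 & sim$dataset$betas <= 1))
  }
})

test_that("noise-free informative probes are exact affine functions of transformed age", {
  spec <- simulation_spec(n_samples = 25, n_cpgs = 10, n_age_cpgs = 1,
                          n_sex_cpgs = 0, noise_sd = 0, probe_fail_rate = 0,
                          slope_range = c(0.1, 0.1),
                          baseline_range = c(0.5, 0.5), seed = 3)
  sim <- generate_dataset(spec)
  cg <- sim$truth$informative_cpg_ids
  t_age <- llin2(sim$truth$true_ages, spec$life_history)
  beta <- sim$dataset$betas[cg, ]
  expect_equal(abs(cor(beta, t_age)), 1)
  fit <- lm(beta ~ t_age)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(abs(unname(coef(fit)[2])), 0.1)
  expect_equal(unname(sim$truth$slopes), unname(coef(fit)[2]))
})

test_that("the noise-free informative block has affine rank at most 2", {
  spec <- simulation_spec(n_samples = 30, n_cpgs = 50, n_age_cpgs = 12,
                          n_sex_cpgs = 0, noise_sd = 0, probe_fail_rate = 0,
                          slope_range = c(0.02, 0.08),
                          baseline_range = c(0.4, 0.6), seed = 4)
  sim <- generate_dataset(spec)
  block <- sim$dataset$betas[sim$truth$informative_cpg_ids, ]
  expect_lte(qr(block)$rank, 2)
})

test_that("the empirical female fraction obeys the binomial law at n = 10000", {
  spec <- simulation_spec(n_samples = 10000, n_cpgs = 3, n_age_cpgs = 0,
                          n_sex_cpgs = 0, probe_fail_rate = 0, n_min_age = 0,
                          seed = 5)
  sim <- generate_dataset(spec)
  frac <- mean(sim$dataset$samples$sex == "female")
  se <- sqrt(spec$sex_ratio * (1 - spec$sex_ratio) / spec$n_samples)
  expect_lt(abs(frac - spec$sex_ratio), 3 * se)
})

test_that("probe failures appear at the configured rate and minimum-age flags hit the oldest", {
  spec <- simulation_spec(n_samples = 50, n_cpgs = 200, probe_fail_rate = 0.05,
                          n_min_age = 2, seed = 6)
  sim <- generate_dataset(spec)
  fail_frac <- mean(sim$dataset$detection_p > 0.05)
  expect_lt(abs(fail_frac - 0.05), 3 * sqrt(0.05 * 0.95 / (50 * 200)))
  flagged <- sim$dataset$samples$age_is_minimum
  expect_equal(sum(flagged), 2)
  expect_true(min(sim$dataset$samples$dental_age[flagged]) >=
                max(sim$dataset$samples$dental_age[!flagged]))
})

test_that("infeasible specs are rejected", {
  expect_error(simulation_spec(n_cpgs = 10, n_age_cpgs = 8, n_sex_cpgs = 5),
               "exceeds")
})

test_that("simulate_to_dir writes files load_dataset reads back unchanged", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(n_samples = 8, n_cpgs = 20, n_age_cpgs = 4,
                          n_sex_cpgs = 2, seed = 7)
  sim <- simulate_to_dir(spec, dir)
  ds <- load_dataset(file.path(dir, "betas.csv"), file.path(dir, "samples.csv"),
                     detection_p_path = file.path(dir, "detection_p.csv"))
  expect_identical(ds$betas, sim$dataset$betas)
  expect_identical(ds$detection_p, sim$dataset$detection_p)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$informative_cpg_ids, sim$truth$informative_cpg_ids)
})
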
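#' Specification for a synthetic methylation dataset
#'
#' Describes a simulated study with the statistical structure the clock
#' analysis assumes: ages spanning the common-dolphin lifespan and skewed
#' toward young animals, a roughly 47:37 female:male ratio, a small block of
#' age-informative CpGs whose beta values drift log-linearly with age, a
#' block of sex-differential CpGs, background probes, beta-scale Gaussian
#' noise, and sporadic probe failures recorded in detection p-values.
#'
#' Defaults emulate the study conditions: 84 samples (before quality
#' control), a 2,000-probe array standing in for the full mammalian
#' methylation array, 40 age-informative and 10 sex-differential CpGs.
#'
#' @param n_samples number of samples.
#' @param n_cpgs total number of CpG probes.
#' @param n_age_cpgs number of age-informative probes.
#' @param n_sex_cpgs number of sex-differential probes (disjoint from the
#'   age-informative ones).
#' @param age_range `c(min, max)` age span in years.
#' @param age_skew shape parameter of the Beta(1, `age_skew`) density from
#'   which relative ages are drawn; values > 1 favor young animals (the
#'   default reproduces a sample mostly aged 0-20 y with a minority of
#'   physically mature adults). Use 1 for uniform ages.
#' @param sex_ratio fraction of females.
#' @param slope_range `c(low, high)` magnitude range of the per-CpG effect of
#'   transformed age on beta; each informative CpG gets a random sign.
#' @param noise_sd beta-scale Gaussian noise standard deviation.
#' @param baseline_range `c(low, high)` range of probe baseline methylation.
#' @param sex_effect beta offset added to male samples at sex-differential
#'   CpGs (sign randomized per CpG).
#' @param probe_fail_rate per-cell probability that the detection p-value
#'   exceeds the 0.05 failure threshold.
#' @param n_min_age number of samples flagged `age_is_minimum`; assigned to
#'   the oldest animals, mirroring field practice where only old, worn teeth
#'   defeat exact growth-layer counts.
#' @param year_range `c(first, last)` collection years, drawn uniformly.
#' @param life_history a [life_history_params()] object used both for the
#'   drift model and as the dataset's transform anchors.
#' @param seed RNG seed for [generate_dataset()].
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 84, n_cpgs = 2000, n_age_cpgs = 40,
                            n_sex_cpgs = 10, age_range = c(0, 34),
                            age_skew = 1.8, sex_ratio = 47 / 84,
                            slope_range = c(0.04, 0.12), noise_sd = 0.02,
                            baseline_range = c(0.25, 0.75), sex_effect = 0.3,
                            probe_fail_rate = 0.002, n_min_age = 2,
                            year_range = c(2000, 2022),
                            life_history = life_history_params(), seed = 1L) {
  if (n_age_cpgs + n_sex_cpgs > n_cpgs) {
    stop("n_age_cpgs + n_sex_cpgs (", n_age_cpgs + n_sex_cpgs,
         ") exceeds n_cpgs (", n_cpgs, ")")
  }
  stopifnot(n_samples >= 1, sex_ratio >= 0, sex_ratio <= 1,
            probe_fail_rate >= 0, probe_fail_rate <= 1, noise_sd >= 0,
            age_skew > 0, length(age_range) == 2, age_range[1] < age_range[2],
            age_range[1] >= 0, n_min_age <= n_samples)
  structure(list(n_samples = n_samples, n_cpgs = n_cpgs,
                 n_age_cpgs = n_age_cpgs, n_sex_cpgs = n_sex_cpgs,
                 age_range = age_range, age_skew = age_skew,
                 sex_ratio = sex_ratio, slope_range = slope_range,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 sex_effect = sex_effect, probe_fail_rate = probe_fail_rate,
                 n_min_age = n_min_age, year_range = year_range,
                 life_history = life_history, seed = seed),
            class = "simulation_spec")
}

#' Generate a synthetic methylation dataset with known ground truth
#'
#' The generative model, per CpG j and sample i with transformed age
#' `T(age_i)` (the [llin2()] transform under `spec$life_history`):
#' age-informative probes follow
#' `beta = clamp(baseline_j + slope_j * T(age_i) + eps, 0, 1)`,
#' sex-differential probes `beta = clamp(baseline_j + effect_j * male_i + eps, 0, 1)`,
#' background probes `beta = clamp(baseline_j + eps, 0, 1)`, with
#' `eps ~ N(0, noise_sd^2)`. Detection p-values are drawn below the 0.05
#' failure threshold except for cells that independently fail with
#' `probe_fail_rate`, which land strictly above it. Metadata (decomposition
#' code, source, collection year) is drawn uniformly from its domain.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional override of `spec$seed`.
#' @return a list with elements `dataset` (a `methylation_dataset`) and
#'   `truth` (class `simulation_truth`: `true_ages`, `true_sexes`,
#'   `informative_cpg_ids`, `sex_cpg_ids`, `slopes`).
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(seed, {
    n <- spec$n_samples
    p <- spec$n_cpgs
    cpg_ids <- sprintf("cg%05d", seq_len(p))
    sample_ids <- sprintf("D%03d", seq_len(n))

    rel <- stats::rbeta(n, 1, spec$age_skew)
    ages <- spec$age_range[1] + rel * diff(spec$age_range)
    sexes <- ifelse(stats::runif(n) < spec$sex_ratio, "female", "male")
    t_age <- llin2(ages, spec$life_history)

    idx_age <- seq_len(spec$n_age_cpgs)
    idx_sex <- seq_len(spec$n_sex_cpgs) + spec$n_age_cpgs
    baselines <- stats::runif(p, spec$baseline_range[1], spec$baseline_range[2])
    slopes <- stats::runif(spec$n_age_cpgs, spec$slope_range[1], spec$slope_range[2]) *
      sample(c(-1, 1), spec$n_age_cpgs, replace = TRUE)
    sex_signs <- sample(c(-1, 1), spec$n_sex_cpgs, replace = TRUE)

    betas <- matrix(baselines, nrow = p, ncol = n,
                    dimnames = list(cpg_ids, sample_ids))
    if (spec$n_age_cpgs > 0) {
      betas[idx_age, ] <- betas[idx_age, , drop = FALSE] + outer(slopes, t_age)
    }
    if (spec$n_sex_cpgs > 0) {
      male <- as.numeric(sexes == "male")
      betas[idx_sex, ] <- betas[idx_sex, , drop = FALSE] +
        outer(sex_signs * spec$sex_effect, male)
    }
    if (spec$noise_sd > 0) {
      betas <- betas + matrix(stats::rnorm(p * n, sd = spec$noise_sd), p, n)
    }
    betas <- pmin(pmax(betas, 0), 1)

    fails <- matrix(stats::runif(p * n) < spec$probe_fail_rate, p, n)
    detp <- matrix(stats::runif(p * n, 0, 0.05), p, n,
                   dimnames = list(cpg_ids, sample_ids))
    detp[fails] <- 0.05 + stats::runif(sum(fails)) * 0.95

    min_flags <- rep(FALSE, n)
    if (spec$n_min_age > 0) {
      min_flags[order(ages, decreasing = TRUE)[seq_len(spec$n_min_age)]] <- TRUE
    }
    samples <- data.frame(
      sample_id = sample_ids,
      dental_age = ages,
      age_is_minimum = min_flags,
      sex = sexes,
      dcc = sample(1:3, n, replace = TRUE),
      source = sample(valid_sources, n, replace = TRUE),
      collection_year = sample(seq(spec$year_range[1], spec$year_range[2]), n,
                               replace = TRUE),
      stringsAsFactors = FALSE)

    dataset <- methylation_dataset(betas, samples, detection_p = detp,
                                   life_history = spec$life_history)
    truth <- structure(list(true_ages = stats::setNames(ages, sample_ids),
                            true_sexes = stats::setNames(sexes, sample_ids),
                            informative_cpg_ids = cpg_ids[idx_age],
                            sex_cpg_ids = cpg_ids[idx_sex],
                            slopes = stats::setNames(slopes, cpg_ids[idx_age])),
                       class = "simulation_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits `betas.csv`, `detection_p.csv`, `samples.csv` and `truth.json` under
#' `out_dir` — the on-disk form [load_dataset()] reads back.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if absent).
#' @param seed optional override of `spec$seed`.
#' @return the generated object from [generate_dataset()], invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir, seed = spec$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_dataset(spec, seed = seed)
  write_dataset(sim$dataset,
                beta_path = file.path(out_dir, "betas.csv"),
                sheet_path = file.path(out_dir, "samples.csv"),
                detection_p_path = file.path(out_dir, "detection_p.csv"))
  jsonlite::write_json(
    list(true_ages = as.list(sim$truth$true_ages),
         true_sexes = as.list(sim$truth$true_sexes),
         informative_cpg_ids = sim$truth$informative_cpg_ids,
         sex_cpg_ids = sim$truth$sex_cpg_ids,
         slopes = as.list(sim$truth$slopes)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
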
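#' Build the relaxed / strict / restricted analysis subsets
#'
#' Three nested sample subsets drive the clock comparisons:
#' \itemize{
#'   \item \emph{relaxed}: every QC-passing sample;
#'   \item \emph{strict}: relaxed minus samples whose dental age is only a
#'     minimum estimate (`age_is_minimum`);
#'   \item \emph{restricted}: relaxed minus samples whose relaxed-LOOCV
#'     absolute error is `error_cutoff` years or more (strictly-less-than
#'     rule: a sample at exactly the cutoff is dropped). Minimum-age samples
#'     fall out automatically when their errors are large, as in practice.
#' }
#'
#' @param dataset the QC-passing `methylation_dataset`.
#' @param relaxed_loocv a `loocv_result` on the relaxed subset covering
#'   every dataset sample.
#' @param error_cutoff years; default 6.
#' @return named list of sample-id vectors: `relaxed`, `strict`,
#'   `restricted`.
#' @export
build_subsets <- function(dataset, relaxed_loocv, error_cutoff = 6) {
  ids <- dataset$sample_ids
  missing_ids <- setdiff(ids, relaxed_loocv$sample_id)
  if (length(missing_ids) > 0) {
    stop("LOOCV result lacks samples: ", paste(missing_ids, collapse = ", "))
  }
  err <- relaxed_loocv$abs_error[match(ids, relaxed_loocv$sample_id)]
  list(relaxed = ids,
       strict = ids[!dataset$samples$age_is_minimum],
       restricted = ids[err < error_cutoff])
}

#' Error-metric suite for age predictions
#'
#' The standard clock-accuracy bundle: median and mean absolute error in
#' years, the Pearson correlation of predicted with dental age, an ordinary
#' least-squares regression of predicted age (response) on dental age
#' (predictor) giving slope, intercept and R-squared, counts of samples with
#' absolute error strictly above 6 and 10 years, and the maximum absolute
#' error. A slope near 1 and intercept near 0 indicate unbiased prediction;
#' a slope below 1 is the signature of regression to the mean (over-ageing
#' the young, under-ageing the old).
#'
#' @param predictions a `loocv_result`, or a numeric vector of predicted
#'   ages (years).
#' @param ages dental ages (years); taken from `predictions` when it is a
#'   `loocv_result`.
#' @param error_thresholds years; errors strictly above each are counted.
#' @return an object of class `eval_report`: list with `n`, `mae_median`,
#'   `mae_mean`, `pearson_r`, `r_squared`, `slope`, `intercept`,
#'   `n_err_gt6`, `n_err_gt10`, `max_abs_error`.
#' @export
evaluate_predictions <- function(predictions, ages = NULL,
                                 error_thresholds = c(6, 10)) {
  if (inherits(predictions, "loocv_result")) {
    ages <- predictions$dental_age
    predictions <- predictions$predicted_age
  }
  stopifnot(length(predictions) == length(ages))
  n <- length(ages)
  if (n < 3) stop("evaluation needs >= 3 samples")
  if (stats::sd(ages) == 0) stop("ages have zero variance; correlation undefined")
  err <- abs(predictions - ages)
  fit <- stats::lm(predictions ~ ages)
  structure(list(
    n = n,
    mae_median = stats::median(err),
    mae_mean = mean(err),
    pearson_r = stats::cor(ages, predictions),
    r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_err_gt6 = sum(err > error_thresholds[1]),
    n_err_gt10 = sum(err > error_thresholds[2]),
    max_abs_error = max(err)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report (n = %d): MAE %.2f y (mean %.2f), r = %.2f, ",
                     "R2 = %.2f, slope %.2f, intercept %.2f\n",
                     "  errors > 6 y: %d; > 10 y: %d; max %.2f y\n"),
              x$n, x$mae_median, x$mae_mean, x$pearson_r, x$r_squared,
              x$slope, x$intercept, x$n_err_gt6, x$n_err_gt10, x$max_abs_error))
  invisible(x)
}

#' Decomposition-condition effect on prediction error
#'
#' Kruskal-Wallis rank-sum test (tie-corrected, asymptotic chi-squared
#' p-value) for differences in the absolute prediction-error distribution
#' across decomposition condition categories. Categories are taken as they
#' occur in the data.
#'
#' @param abs_errors absolute prediction errors, years.
#' @param dcc per-sample decomposition condition codes.
#' @return list of class `covariate_test`: `test_name`, `statistic` (H),
#'   `df`, `p_value`, `group_sizes`.
#' @export
decomposition_effect <- function(abs_errors, dcc) {
  stopifnot(length(abs_errors) == length(dcc))
  groups <- factor(dcc)
  if (nlevels(groups) < 2) stop("need >= 2 decomposition categories")
  if (stats::sd(abs_errors) == 0) {
    # complete ties: every rank equal, H = 0 by definition (the tie-corrected
    # statistic is 0/0 numerically, so handle the degenerate case explicitly)
    return(structure(list(test_name = "kruskal_wallis_dcc", statistic = 0,
                          df = nlevels(groups) - 1, p_value = 1,
                          group_sizes = table(groups)),
                     class = "covariate_test"))
  }
  kw <- stats::kruskal.test(abs_errors, groups)
  structure(list(test_name = "kruskal_wallis_dcc",
                 statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, group_sizes = table(groups)),
            class = "covariate_test")
}

#' Storage-duration effect on prediction error
#'
#' Three linked analyses of whether archival time biases the clock:
#' (i) Spearman rank correlation of absolute error with storage years;
#' (ii) OLS of error on storage alone; (iii) OLS of error on storage plus
#' chronological age, since error scales with age and storage often tracks
#' age structure in archives. Residual normality of each regression is
#' checked with a Shapiro-Wilk test.
#'
#' @param abs_errors absolute prediction errors, years.
#' @param storage_years per-sample storage durations, years.
#' @param ages per-sample dental ages, years.
#' @return list of class `storage_effect` with elements `spearman`
#'   (`rho`, `p_value`), `unadjusted` and `age_adjusted` (each with
#'   `beta_storage`, `se_storage`, `p_storage`, and for the adjusted model
#'   `beta_age`, `se_age`, `p_age`, plus `r_squared`, `shapiro_p`).
#' @export
storage_effect <- function(abs_errors, storage_years, ages) {
  stopifnot(length(abs_errors) == length(storage_years),
            length(abs_errors) == length(ages))
  if (length(abs_errors) < 4) stop("storage-effect test needs >= 4 samples")
  if (stats::sd(storage_years) == 0) {
    stop("storage durations are constant; correlation undefined")
  }
  sp <- suppressWarnings(stats::cor.test(abs_errors, storage_years,
                                         method = "spearman"))
  summarize_fit <- function(fit) {
    sm <- summary(fit)
    co <- sm$coefficients
    out <- list(beta_storage = co["storage_years", "Estimate"],
                se_storage = co["storage_years", "Std. Error"],
                p_storage = co["storage_years", "Pr(>|t|)"],
                r_squared = sm$r.squared,
                shapiro_p = stats::shapiro.test(stats::residuals(fit))$p.value)
    if ("ages" %in% rownames(co)) {
      out$beta_age <- co["ages", "Estimate"]
      out$se_age <- co["ages", "Std. Error"]
      out$p_age <- co["ages", "Pr(>|t|)"]
    }
    out
  }
  structure(list(
    spearman = list(rho = unname(sp$estimate), p_value = sp$p.value),
    unadjusted = summarize_fit(stats::lm(abs_errors ~ storage_years)),
    age_adjusted = summarize_fit(stats::lm(abs_errors ~ storage_years + ages))),
    class = "storage_effect")
}
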
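#' Per-sample fraction of failed probes
#'
#' A probe measurement is failed when its detection p-value strictly exceeds
#' `p_threshold` (background-level signal). Returns, for each sample, the
#' failed-cell count divided by the number of probes.
#'
#' @param dataset a `methylation_dataset` carrying detection p-values.
#' @param p_threshold failure threshold on the detection p-value, in (0,1).
#' @return named numeric vector of per-sample failed fractions in [0,1].
#' @export
flag_failed_probes <- function(dataset, p_threshold = 0.05) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (is.null(dataset$detection_p)) {
    stop("detection p-values absent: probe-failure QC step cannot run ",
         "(pass the detection matrix or skip this step explicitly)")
  }
  colMeans(dataset$detection_p > p_threshold)
}

#' Flag samples by failed-probe fraction
#'
#' Samples whose failed fraction strictly exceeds `max_fraction` (default:
#' more than 1% of probes failed) are fraction outliers.
#'
#' @param fractions named per-sample failed fractions from
#'   [flag_failed_probes()].
#' @param max_fraction tolerated failed fraction, in (0,1).
#' @return character vector of flagged sample ids.
#' @export
flag_fraction_outliers <- function(fractions, max_fraction = 0.01) {
  stopifnot(max_fraction > 0, max_fraction < 1)
  names(fractions)[fractions > max_fraction]
}

#' Flag multivariate sample outliers in principal-component space
#'
#' Centers the beta matrix per CpG (no scaling, no normalisation), projects
#' samples onto the top principal components, and computes each sample's
#' Euclidean distance to the sample centroid in that space. Samples whose
#' distance strictly exceeds mean + `sd_threshold` x SD of the distances are
#' flagged. This single distance criterion unifies the usual PCA-plus-
#' hierarchical-clustering inspection into one order-invariant, testable
#' rule.
#'
#' @param dataset a `methylation_dataset` with >= 3 samples.
#' @param n_components number of principal components; default (`NULL`) uses
#'   the components explaining >= 90% of variance, capped at 5.
#' @param sd_threshold multiplier on the SD of centroid distances.
#' @return character vector of flagged sample ids.
#' @export
flag_multivariate_outliers <- function(dataset, n_components = NULL,
                                       sd_threshold = 2) {
  n <- n_samples(dataset)
  if (n < 3) stop("multivariate outlier detection needs >= 3 samples")
  stopifnot(sd_threshold > 0)
  if (!is.null(n_components) && n_components >= n) {
    stop("n_components (", n_components, ") must be < n_samples (", n, ")")
  }
  x <- t(dataset$betas - rowMeans(dataset$betas)) # samples x CpGs, centred per CpG
  if (all(abs(x) < .Machine$double.eps * 10)) return(character(0))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  if (is.null(n_components)) {
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_components <- min(which(cumvar >= 0.9)[1], 5L, ncol(pc$x))
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  cut <- mean(d) + sd_threshold * stats::sd(d)
  dataset$sample_ids[d > cut]
}

#' Assemble a sample quality-control report
#'
#' Runs the probe-failure and multivariate outlier steps and merges their
#' verdicts with any manual exclusions into one report listing every sample
#' as retained or excluded with reason codes. When detection p-values are
#' absent the probe-failure step is skipped with a warning.
#'
#' @param dataset a `methylation_dataset`.
#' @param p_threshold,max_fraction,n_components,sd_threshold thresholds
#'   passed to the component steps.
#' @param manual_exclusions sample ids excluded for reasons outside the
#'   methylation data (e.g. inconsistent life-history records).
#' @return an object of class `qc_report` with elements
#'   `failed_probe_fraction`, `fraction_outliers`, `multivariate_outliers`,
#'   `excluded` (data.frame of sample_id, reasons), `retained`.
#' @export
qc_report <- function(dataset, p_threshold = 0.05, max_fraction = 0.01,
                      n_components = NULL, sd_threshold = 2,
                      manual_exclusions = character(0)) {
  unknown <- setdiff(manual_exclusions, dataset$sample_ids)
  if (length(unknown) > 0) {
    stop("manual exclusion ids not in dataset: ", paste(unknown, collapse = ", "))
  }
  if (is.null(dataset$detection_p)) {
    warning("detection p-values absent; probe-failure QC step skipped")
    fractions <- stats::setNames(rep(NA_real_, n_samples(dataset)),
                                 dataset$sample_ids)
    frac_out <- character(0)
  } else {
    fractions <- flag_failed_probes(dataset, p_threshold)
    frac_out <- flag_fraction_outliers(fractions, max_fraction)
  }
  mv_out <- flag_multivariate_outliers(dataset, n_components, sd_threshold)

  reasons <- list()
  for (id in frac_out) reasons[[id]] <- c(reasons[[id]], "failed_probe_fraction")
  for (id in mv_out) reasons[[id]] <- c(reasons[[id]], "multivariate_outlier")
  for (id in manual_exclusions) reasons[[id]] <- c(reasons[[id]], "manual")
  excluded_ids <- dataset$sample_ids[dataset$sample_ids %in% names(reasons)]
  excluded <- data.frame(
    sample_id = excluded_ids,
    reasons = vapply(reasons[excluded_ids], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(failed_probe_fraction = fractions,
                 fraction_outliers = frac_out,
                 multivariate_outliers = mv_out,
                 excluded = excluded,
                 retained = setdiff(dataset$sample_ids, excluded_ids)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d retained, %d excluded (%d fraction, %d multivariate)\n",
              length(x$retained), nrow(x$excluded),
              length(x$fraction_outliers), length(x$multivariate_outliers)))
  invisible(x)
}

#' Apply a quality-control report to a dataset
#'
#' Restricts the dataset to the report's retained samples. Idempotent:
#' applying the same report twice equals applying it once.
#'
#' @param dataset the `methylation_dataset` the report was derived from.
#' @param report a [qc_report()].
#' @return the retained-samples `methylation_dataset`.
#' @export
apply_qc <- function(dataset, report) {
  stopifnot(inherits(report, "qc_report"))
  keep <- intersect(dataset$sample_ids, report$retained)
  if (length(keep) == 0) stop("quality control would exclude every sample")
  if (length(keep) == n_samples(dataset)) return(dataset)
  subset_samples(dataset, keep)
}
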
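#' Fit an elastic-net epigenetic clock
#'
#' Regresses log-linearly transformed dental age on beta values with an
#' elastic-net penalty. The penalty strength lambda is chosen by internal
#' k-fold cross-validation (minimum mean CV error rule) with a seeded fold
#' assignment, so identical inputs and seed give an identical model.
#' Features are standardized internally for fitting; coefficients are
#' returned on the original beta scale.
#'
#' @param dataset a `methylation_dataset` (>= 3 samples, no missing betas).
#' @param alpha elastic-net mixing parameter in [0,1] (0 = ridge,
#'   1 = LASSO).
#' @param seed integer seed; fold assignment is derived from it.
#' @param lh life-history anchors; defaults to the dataset's.
#' @param asm ASM anchor(s) for the age transform: a scalar, or a per-sample
#'   vector for sex-specific anchoring. Default: pooled ASM.
#' @param nfolds internal CV folds for lambda (default 10, reduced to the
#'   sample count when smaller).
#' @return a [clock_model()]. If every feature has zero variance the model
#'   degenerates to an intercept-only predictor (intercept = mean
#'   transformed age, `lambda = Inf`).
#' @export
fit_clock <- function(dataset, alpha = 0.5, seed = 1L,
                      lh = dataset$life_history, asm = NULL, nfolds = 10) {
  n <- n_samples(dataset)
  if (n < 3) stop("fit_clock needs >= 3 samples, got ", n)
  stopifnot(alpha >= 0, alpha <= 1)
  x <- t(dataset$betas)
  if (any(!is.finite(x))) stop("missing or non-finite beta values; no silent imputation")
  asm <- asm %||% lh$asm_pooled
  if (length(asm) == 1) asm <- rep(asm, n)
  y <- llin2(dataset$samples$dental_age, lh, asm = asm)

  if (all(matrixStats_colVars(x) == 0)) {
    return(clock_model(alpha, Inf, mean(y), stats::setNames(numeric(0), character(0)),
                       life_history = lh, n_train = n))
  }
  nfolds <- min(nfolds, n)
  foldid <- with_seed(derive_seed(seed, "lambda_cv"),
                      sample(rep_len(seq_len(nfolds), n)))
  cv <- quiet_cv_glmnet(x, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE, family = "gaussian")
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- b[-1, 1]
  clock_model(alpha, cv$lambda.min, intercept = b[1, 1],
              coefficients = coefs[coefs != 0], life_history = lh, n_train = n)
}

# column variances without extra dependencies
matrixStats_colVars <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

#' Predict ages from a fitted clock
#'
#' Computes `intercept + sum(coef * beta)` per sample and, for
#' `type = "years"`, inverts the log-linear transform.
#'
#' @param object a `clock_model`.
#' @param dataset a `methylation_dataset` whose betas cover the model's
#'   CpGs.
#' @param type `"years"` (default) or `"transformed"`.
#' @param asm ASM anchor(s) for the inverse transform; scalar or per-sample.
#' @param ... unused.
#' @return numeric vector of predictions, named by sample id.
#' @export
predict.clock_model <- function(object, dataset, type = c("years", "transformed"),
                                asm = NULL, ...) {
  type <- match.arg(type)
  cpgs <- names(object$coefficients)
  missing_cpgs <- setdiff(cpgs, dataset$cpg_ids)
  if (length(missing_cpgs) > 0) {
    stop("dataset lacks model CpGs: ", paste(missing_cpgs, collapse = ", "))
  }
  lin <- rep(object$intercept, n_samples(dataset))
  if (length(cpgs) > 0) {
    lin <- lin + drop(crossprod(dataset$betas[cpgs, , drop = FALSE],
                                object$coefficients))
  }
  names(lin) <- dataset$sample_ids
  if (type == "transformed") return(lin)
  asm <- asm %||% object$life_history$asm_pooled
  stats::setNames(llin2_inverse(lin, object$life_history, asm = asm),
                  dataset$sample_ids)
}

#' Select the elastic-net mixing parameter by repeated subset validation
#'
#' For each of `n_subsets` seeded random splits (train fraction 2/3 by
#' default), fits a clock at every alpha in the grid (lambda by internal CV
#' on the training part) and records the held-out mean squared error on the
#' transformed-age scale. The alpha with the lowest median MSE across
#' subsets wins; ties break toward the larger alpha (the sparser model).
#'
#' @param dataset a `methylation_dataset` (>= 6 samples).
#' @param grid alpha values to scan; default 0, 0.1, ..., 1.
#' @param n_subsets number of random splits (default 20).
#' @param train_fraction fraction of samples used for training (default 2/3).
#' @param seed integer seed; split and fold randomness derive from it.
#' @param lh,asm,nfolds passed to [fit_clock()].
#' @return an object of class `alpha_search` with elements `grid`,
#'   `median_mse`, `mse` (subset x alpha matrix), `n_subsets`,
#'   `subset_fraction`, `selected_alpha`.
#' @export
select_alpha <- function(dataset, grid = seq(0, 1, by = 0.1), n_subsets = 20,
                         train_fraction = 2 / 3, seed = 1L,
                         lh = dataset$life_history, asm = NULL, nfolds = 10) {
  n <- n_samples(dataset)
  if (n < 6) stop("alpha selection needs >= 6 samples")
  if (length(grid) == 0 || any(grid < 0 | grid > 1)) {
    stop("alpha grid must be non-empty with all values in [0,1]")
  }
  mse <- matrix(NA_real_, n_subsets, length(grid),
                dimnames = list(NULL, paste0("alpha_", grid)))
  y_all <- llin2(dataset$samples$dental_age, lh,
                 asm = if (is.null(asm)) lh$asm_pooled else asm)
  for (s in seq_len(n_subsets)) {
    idx <- with_seed(derive_seed(seed, paste0("alpha_subset:", s)),
                     sample(n, size = floor(train_fraction * n)))
    train <- subset_samples(dataset, dataset$sample_ids[idx])
    test <- subset_samples(dataset, dataset$sample_ids[-idx])
    sub_seed <- derive_seed(seed, paste0("alpha_fit:", s))
    asm_train <- if (!is.null(asm) && length(asm) > 1) asm[idx] else asm
    for (a in seq_along(grid)) {
      model <- fit_clock(train, alpha = grid[a], seed = sub_seed, lh = lh,
                         asm = asm_train, nfolds = nfolds)
      pred <- predict(model, test, type = "transformed")
      mse[s, a] <- mean((pred - y_all[-idx])^2)
    }
  }
  med <- apply(mse, 2, stats::median)
  best <- max(grid[med == min(med)]) # ties -> larger alpha (sparser)
  structure(list(grid = grid, median_mse = stats::setNames(med, NULL),
                 mse = mse, n_subsets = n_subsets,
                 subset_fraction = train_fraction, selected_alpha = best),
            class = "alpha_search")
}

#' @export
print.alpha_search <- function(x, ...) {
  cat(sprintf("alpha_search: selected alpha = %.1f (median MSE %.4g over %d subsets)\n",
              x$selected_alpha, min(x$median_mse), x$n_subsets))
  invisible(x)
}

#' Leave-one-out cross-validated age predictions
#'
#' For each sample, fits a fresh clock on the remaining samples (internal
#' lambda CV re-run, fold assignment seeded deterministically from the
#' left-out sample's id) and predicts the held-out sample's age in years.
#' Because per-fold seeds derive from sample ids, the result is invariant to
#' sample order, and an independent loop that materializes each n-1 dataset
#' and calls [fit_clock()] with `derive_seed(seed, paste0("loo:", id))`
#' reproduces it exactly.
#'
#' @param dataset a `methylation_dataset` (>= 4 samples).
#' @param alpha elastic-net mixing parameter, held fixed across folds.
#' @param seed integer top-level seed.
#' @param lh,nfolds passed to [fit_clock()].
#' @param asm scalar or per-sample ASM anchors (sex-specific clocks).
#' @return an object of class `loocv_result`: a data.frame with columns
#'   `sample_id`, `dental_age`, `predicted_age`, `residual`, `abs_error`
#'   (years), ordered as the dataset.
#' @export
loocv_predict <- function(dataset, alpha = 0.5, seed = 1L,
                          lh = dataset$life_history, asm = NULL, nfolds = 10) {
  n <- n_samples(dataset)
  if (n < 4) stop("LOOCV needs >= 4 samples")
  ids <- dataset$sample_ids
  if (!is.null(asm) && length(asm) == 1) asm <- rep(asm, n)
  preds <- vapply(seq_len(n), function(i) {
    id <- ids[i]
    train <- subset_samples(dataset, ids[-i])
    model <- tryCatch(
      fit_clock(train, alpha = alpha, seed = derive_seed(seed, paste0("loo:", id)),
                lh = lh, asm = if (is.null(asm)) NULL else asm[-i],
                nfolds = nfolds),
      error = function(e) stop("LOOCV fold leaving out '", id, "' failed: ",
                               conditionMessage(e)))
    test <- subset_samples(dataset, id)
    predict(model, test, type = "years",
            asm = if (is.null(asm)) NULL else asm[i])[[1]]
  }, numeric(1))
  ages <- dataset$samples$dental_age
  structure(data.frame(sample_id = ids, dental_age = ages,
                       predicted_age = preds, residual = preds - ages,
                       abs_error = abs(preds - ages),
                       stringsAsFactors = FALSE),
            class = c("loocv_result", "data.frame"))
}
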
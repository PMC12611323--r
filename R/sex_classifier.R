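#' Fit a methylation-based sex classifier
#'
#' Binomial elastic-net regression of sex on beta values, with sex encoded
#' 0 = female, 1 = male and the default mixing parameter alpha = 0.4.
#' Lambda is chosen by seeded internal cross-validation; betas are
#' standardized internally and coefficients returned on the beta scale.
#'
#' @param dataset a `methylation_dataset` containing both sexes (>= 3
#'   samples per sex).
#' @param alpha elastic-net mixing parameter (default 0.4).
#' @param seed integer seed for the lambda CV folds.
#' @param nfolds internal CV folds (default 10, reduced for small n).
#' @param decision_threshold probability cutoff: male iff P(male) strictly
#'   exceeds it (default 0.5; exact ties resolve to female).
#' @return an object of class `sex_model` with `alpha`, `lambda`,
#'   `intercept`, `coefficients` (nonzero only), `decision_threshold`.
#' @export
fit_sex <- function(dataset, alpha = 0.4, seed = 1L, nfolds = 10,
                    decision_threshold = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, decision_threshold > 0, decision_threshold < 1)
  y <- as.integer(dataset$samples$sex == "male")
  if (min(table(factor(y, levels = 0:1))) < 3) {
    stop("sex classification needs >= 3 samples of each sex")
  }
  x <- t(dataset$betas)
  n <- nrow(x)
  nfolds <- min(nfolds, n)
  foldid <- with_seed(derive_seed(seed, "sex_cv"),
                      sample(rep_len(seq_len(nfolds), n)))
  cv <- quiet_cv_glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = TRUE)
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- b[-1, 1]
  structure(list(alpha = alpha, lambda = cv$lambda.min, intercept = b[1, 1],
                 coefficients = coefs[coefs != 0],
                 decision_threshold = decision_threshold),
            class = "sex_model")
}

#' @export
print.sex_model <- function(x, ...) {
  cat(sprintf("sex_model: alpha %.2f, lambda %.4g, %d retained CpGs\n",
              x$alpha, x$lambda, length(x$coefficients)))
  invisible(x)
}

#' Predict sex from methylation
#'
#' Computes P(male) from the logistic linear predictor and labels a sample
#' male only when the probability strictly exceeds the decision threshold.
#'
#' @param model a `sex_model`.
#' @param dataset a `methylation_dataset` covering the model's CpGs.
#' @return data.frame with `sample_id`, `p_male`, `predicted_sex`, and
#'   `true_sex` from the sample sheet.
#' @export
predict_sex <- function(model, dataset) {
  stopifnot(inherits(model, "sex_model"))
  cpgs <- names(model$coefficients)
  missing_cpgs <- setdiff(cpgs, dataset$cpg_ids)
  if (length(missing_cpgs) > 0) {
    stop("dataset lacks model CpGs: ", paste(missing_cpgs, collapse = ", "))
  }
  lin <- rep(model$intercept, n_samples(dataset))
  if (length(cpgs) > 0) {
    lin <- lin + drop(crossprod(dataset$betas[cpgs, , drop = FALSE],
                                model$coefficients))
  }
  p <- stats::plogis(lin)
  data.frame(sample_id = dataset$sample_ids, p_male = unname(p),
             predicted_sex = ifelse(p > model$decision_threshold, "male", "female"),
             true_sex = dataset$samples$sex, stringsAsFactors = FALSE)
}
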
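#' Physical-maturity labels from sex and dental age
#'
#' Females are physically mature at 18 years and males at 20 years, both
#' thresholds inclusive.
#'
#' @param samples a sample metadata data.frame with `sex` and `dental_age`.
#' @param thresholds named vector `c(female = 18, male = 20)` in years.
#' @return factor with levels `immature`, `mature`, one per sample.
#' @export
label_maturity <- function(samples, thresholds = c(female = 18, male = 20)) {
  if (!all(samples$sex %in% names(thresholds))) {
    stop("unknown sex value(s): ",
         paste(setdiff(unique(samples$sex), names(thresholds)), collapse = ", "))
  }
  mature <- samples$dental_age >= thresholds[samples$sex]
  factor(ifelse(mature, "mature", "immature"), levels = c("immature", "mature"))
}

# Elastic net with alpha and lambda chosen jointly by k-fold internal CV on
# the training data; ties in CV error break toward the larger (sparser) alpha.
fit_enr_nested <- function(dataset, asm, seed, grid = seq(0, 1, by = 0.1),
                           nfolds = 5, lh = dataset$life_history) {
  n <- n_samples(dataset)
  x <- t(dataset$betas)
  y <- llin2(dataset$samples$dental_age, lh, asm = asm)
  nfolds <- min(nfolds, n)
  foldid <- with_seed(derive_seed(seed, "enr_cv"),
                      sample(rep_len(seq_len(nfolds), n)))
  best <- NULL
  for (a in grid) {
    cv <- quiet_cv_glmnet(x, y, alpha = a, foldid = foldid,
                            standardize = TRUE, family = "gaussian")
    cvm <- min(cv$cvm)
    if (is.null(best) || cvm <= best$cvm) best <- list(alpha = a, cv = cv, cvm = cvm)
  }
  b <- as.matrix(stats::coef(best$cv, s = "lambda.min"))
  coefs <- b[-1, 1]
  clock_model(best$alpha, best$cv$lambda.min, intercept = b[1, 1],
              coefficients = coefs[coefs != 0], life_history = lh, n_train = n)
}

#' Fit the hybrid maturity-gated age model
#'
#' Three components, all trained on the same beta features: (1) a random
#' forest classifier (default 1000 trees) predicting physical maturity;
#' (2) an elastic net trained on all individuals; (3) an elastic net trained
#' on physically mature individuals only, to sharpen predictions in old
#' animals. Both elastic nets regress log-linearly transformed age anchored
#' on each sample's sex-specific ASM (7.5 y female / 8.8 y male), with alpha
#' and lambda chosen by 5-fold internal cross-validation.
#'
#' @param dataset a `methylation_dataset`.
#' @param seed integer seed; forest and CV randomness derive from it.
#' @param n_trees random-forest size.
#' @param maturity_thresholds named vector `c(female = , male = )`, years.
#' @param alpha_grid alpha values scanned by the nested CV.
#' @param min_mature minimum number of physically mature samples required to
#'   train the mature-only elastic net.
#' @param lh life-history anchors; sex-specific ASM values are taken from it.
#' @return an object of class `hybrid_model` with elements `rfc`, `enr_all`,
#'   `enr_mature`, `maturity_thresholds`, `lh`, `seed`.
#' @export
fit_hybrid <- function(dataset, seed = 1L, n_trees = 1000,
                       maturity_thresholds = c(female = 18, male = 20),
                       alpha_grid = seq(0, 1, by = 0.1), min_mature = 10,
                       lh = dataset$life_history) {
  labels <- label_maturity(dataset$samples, maturity_thresholds)
  n_mat <- sum(labels == "mature")
  if (n_mat < min_mature) {
    stop("only ", n_mat, " physically mature samples; the mature-only clock ",
         "requires at least ", min_mature)
  }
  if (length(unique(labels)) < 2) stop("both maturity classes must be present")
  x <- t(dataset$betas)
  rfc <- with_seed(derive_seed(seed, "rfc"),
                   randomForest::randomForest(x = x, y = labels, ntree = n_trees))
  asm_all <- sex_asm(dataset$samples$sex, lh)
  enr_all <- fit_enr_nested(dataset, asm = asm_all,
                            seed = derive_seed(seed, "enr_all"),
                            grid = alpha_grid, lh = lh)
  mature_ids <- dataset$sample_ids[labels == "mature"]
  ds_mat <- subset_samples(dataset, mature_ids)
  enr_mature <- fit_enr_nested(ds_mat, asm = sex_asm(ds_mat$samples$sex, lh),
                               seed = derive_seed(seed, "enr_mature"),
                               grid = alpha_grid, lh = lh)
  structure(list(rfc = rfc, enr_all = enr_all, enr_mature = enr_mature,
                 maturity_thresholds = maturity_thresholds, lh = lh,
                 n_trees = n_trees, seed = seed),
            class = "hybrid_model")
}

sex_asm <- function(sex, lh) {
  ifelse(sex == "female", lh$asm_female, lh$asm_male)
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: RFC %d trees; ENR-all alpha %.1f (%d CpGs); ENR-mature alpha %.1f (%d CpGs)\n",
              x$n_trees, x$enr_all$alpha, n_retained_cpgs(x$enr_all),
              x$enr_mature$alpha, n_retained_cpgs(x$enr_mature)))
  invisible(x)
}

#' Predict ages with the hybrid model
#'
#' Each sample's age is the convex combination
#' `(1 - p) * age_all + p * age_mature`, where `p` is the random-forest
#' probability of physical maturity and the two ages are the component
#' elastic nets' predictions inverted through the sex-specific log-linear
#' transform (the gestation correction lives inside that inverse).
#'
#' @param model a `hybrid_model`.
#' @param dataset a `methylation_dataset` covering the model's CpGs.
#' @param gate optional override of the maturity probability (scalar or
#'   per-sample vector in [0,1]); `NULL` uses the random forest. Forcing 0
#'   or 1 reduces the hybrid to the all-samples or mature-only clock.
#' @return data.frame with columns `sample_id`, `p_mature`, `pred_all`,
#'   `pred_mature`, `predicted_age` (years).
#' @export
predict_hybrid <- function(model, dataset, gate = NULL) {
  stopifnot(inherits(model, "hybrid_model"))
  if (is.null(gate)) {
    x <- t(dataset$betas)
    p <- stats::predict(model$rfc, newdata = x, type = "prob")[, "mature"]
  } else {
    stopifnot(all(gate >= 0 & gate <= 1))
    p <- rep_len(gate, n_samples(dataset))
  }
  asm <- sex_asm(dataset$samples$sex, model$lh)
  pred_all <- predict(model$enr_all, dataset, type = "years", asm = asm)
  pred_mat <- predict(model$enr_mature, dataset, type = "years", asm = asm)
  data.frame(sample_id = dataset$sample_ids, p_mature = unname(p),
             pred_all = unname(pred_all), pred_mature = unname(pred_mat),
             predicted_age = unname((1 - p) * pred_all + p * pred_mat),
             stringsAsFactors = FALSE)
}

#' Deterministic stratified fold assignment
#'
#' Assigns each stratum's members to `k` folds as evenly as possible, with a
#' seeded shuffle inside each stratum. Exported so that independent
#' re-executions of the cross-validation protocol can reproduce the folds.
#'
#' @param labels per-sample stratum labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample, in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- with_seed(derive_seed(seed, paste0("fold:", lv)),
                            sample(rep_len(seq_len(k), length(idx))))
  }
  folds
}

#' Cross-validate the hybrid model
#'
#' k-fold cross-validation (default 5) stratified by maturity label so every
#' training fold contains mature animals. In each fold the forest and both
#' elastic nets are refit on the training data and the held-out samples are
#' predicted; out-of-fold predictions are assembled into one per-sample
#' report in dataset order.
#'
#' @param dataset a `methylation_dataset`.
#' @param k number of folds (>= 2); `k = n` coincides with LOOCV.
#' @param seed integer seed.
#' @param gate optional maturity-probability override forwarded to
#'   [predict_hybrid()]; `gate = 0` reduces the cross-validation to the
#'   all-samples clock alone.
#' @param min_mature minimum number of mature samples the full dataset must
#'   contain for the hybrid analysis to run; each training fold, which holds
#'   roughly a `(k-1)/k` share of them, requires the proportional minimum.
#' @param ... passed to [fit_hybrid()].
#' @return a `loocv_result`-shaped data.frame (`sample_id`, `dental_age`,
#'   `predicted_age`, `residual`, `abs_error`).
#' @export
cross_validate_hybrid <- function(dataset, k = 5, seed = 1L, gate = NULL,
                                  min_mature = 10, ...) {
  stopifnot(k >= 2)
  labels <- label_maturity(dataset$samples)
  n_mat <- sum(labels == "mature")
  if (n_mat < min_mature) {
    stop("only ", n_mat, " physically mature samples; hybrid cross-validation ",
         "requires at least ", min_mature)
  }
  fold_min <- max(2, floor(min_mature * (k - 1) / k))
  folds <- stratified_folds(labels, k, seed)
  for (f in seq_len(k)) {
    if (sum(labels[folds != f] == "mature") == 0) {
      stop("training fold ", f, " contains no mature samples; reduce k or ",
           "check the maturity labels")
    }
  }
  preds <- rep(NA_real_, n_samples(dataset))
  for (f in seq_len(k)) {
    train <- subset_samples(dataset, dataset$sample_ids[folds != f])
    test <- subset_samples(dataset, dataset$sample_ids[folds == f])
    model <- fit_hybrid(train, seed = derive_seed(seed, paste0("hybrid_fold:", f)),
                        min_mature = fold_min, ...)
    preds[folds == f] <- predict_hybrid(model, test, gate = gate)$predicted_age
  }
  ages <- dataset$samples$dental_age
  structure(data.frame(sample_id = dataset$sample_ids, dental_age = ages,
                       predicted_age = preds, residual = preds - ages,
                       abs_error = abs(preds - ages), stringsAsFactors = FALSE),
            class = c("loocv_result", "data.frame"))
}
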
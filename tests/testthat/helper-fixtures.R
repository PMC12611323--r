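# Small deterministic fixtures built in code.

# A hand-sized dataset with random betas (uniform, no structure) and simple
# metadata; ages default to an even spread over 0-30 y.
toy_dataset <- function(n = 6, p = 8, seed = 1, ages = NULL, sexes = NULL,
                        betas = NULL, detection_p = NULL, min_age_flags = NULL,
                        dcc = NULL, storage = NULL) {
  ids <- sprintf("S%02d", seq_len(n))
  cpgs <- sprintf("cg%03d", seq_len(p))
  if (is.null(betas)) {
    betas <- matrix(withr_seeded_runif(p * n, seed), p, n)
  }
  dimnames(betas) <- list(cpgs, ids)
  if (!is.null(detection_p)) dimnames(detection_p) <- list(cpgs, ids)
  ages <- ages %||% seq(0, 30, length.out = n)
  sexes <- sexes %||% rep(c("female", "male"), length.out = n)
  samples <- data.frame(
    sample_id = ids, dental_age = ages,
    age_is_minimum = min_age_flags %||% rep(FALSE, n),
    sex = sexes, dcc = dcc %||% rep(1:3, length.out = n),
    source = rep("bycatch", n),
    collection_year = if (is.null(storage)) rep(2014, n) else 2023 - storage,
    stringsAsFactors = FALSE)
  methylation_dataset(betas, samples, detection_p = detection_p)
}

withr_seeded_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runif(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force LOOCV oracle: materializes every n-1 dataset and
# calls fit_clock directly, using the documented per-fold seed rule.
brute_force_loocv <- function(dataset, alpha, seed) {
  ids <- dataset$sample_ids
  sapply(seq_along(ids), function(i) {
    train <- subset_samples(dataset, ids[-i])
    model <- fit_clock(train, alpha = alpha,
                       seed = derive_seed(seed, paste0("loo:", ids[i])))
    predict(model, subset_samples(dataset, ids[i]))[[1]]
  })
}
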
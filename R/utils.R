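#' Derive a stage- or fold-specific seed from a top-level seed
#'
#' All randomness in the package flows from one user-supplied seed. Stage
#' seeds are derived by hashing a character key (the stage name, a left-out
#' sample id, ...) together with the top-level seed, so adding a stage or
#' permuting sample order never perturbs another stage's random stream.
#'
#' The rule: fold the key's UTF-8 bytes into an integer with a 31-bit
#' polynomial hash (base 131, modulus 2^31 - 1) and combine with the seed.
#'
#' @param seed integer top-level seed.
#' @param key character scalar naming the consumer of the derived stream.
#' @return an integer in [0, 2^31 - 2], usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so package functions never disturb it.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Format doubles so they survive a text round-trip bit-identically.
# 17 significant digits are sufficient for exact IEEE-754 double round-trip.
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cv.glmnet emits advisory warnings on small folds ("grouped=FALSE enforced",
# "fewer than 8 observations"); they are expected on leave-one-out-sized
# training sets and are muffled so real warnings stay visible.
quiet_cv_glmnet <- function(...) {
  # compute the full lambda path: the default early-stopping rules (fdev,
  # devmax) truncate it once the fit saturates, which leaves a visibly
  # shrunken model on near-noise-free data instead of the interpolating one
  old <- glmnet::glmnet.control()
  glmnet::glmnet.control(fdev = 0, devmax = 1)
  on.exit(do.call(glmnet::glmnet.control, old[c("fdev", "devmax")]))
  withCallingHandlers(
    glmnet::cv.glmnet(...),
    warning = function(w) {
      if (grepl("grouped=FALSE enforced|fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
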
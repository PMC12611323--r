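#' Life-history parameters anchoring the age transform
#'
#' Bundles the age at sexual maturity (ASM) and gestation anchors of the
#' log-linear age transformation. Defaults are the common-dolphin values for
#' Aotearoa New Zealand: female ASM 7.5 y, male ASM 8.8 y (pooled 8.15 y) and
#' a gestation length of 1.05 y. Override them to port the pipeline to
#' another species.
#'
#' @param asm_female female age at sexual maturity, years.
#' @param asm_male male age at sexual maturity, years.
#' @param asm_pooled pooled ASM anchor used by the standard (non-hybrid)
#'   clock; defaults to the mean of the sex-specific values.
#' @param gestation gestation length, years; must be smaller than the pooled
#'   ASM.
#' @param max_lifespan maximum plausible age, years; ages above it are
#'   rejected at the data boundary.
#' @return an object of class `life_history_params`.
#' @export
life_history_params <- function(asm_female = 7.5, asm_male = 8.8,
                                asm_pooled = (asm_female + asm_male) / 2,
                                gestation = 1.05, max_lifespan = 60) {
  vals <- c(asm_female = asm_female, asm_male = asm_male,
            asm_pooled = asm_pooled, gestation = gestation,
            max_lifespan = max_lifespan)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all life-history parameters must be finite and strictly positive")
  }
  if (gestation >= asm_pooled) {
    stop("gestation (", gestation, " y) must be smaller than the pooled ASM (",
         asm_pooled, " y)")
  }
  structure(as.list(vals), class = "life_history_params")
}

#' @export
print.life_history_params <- function(x, ...) {
  cat("Life-history parameters (years):\n")
  cat(sprintf("  ASM female %.2f | male %.2f | pooled %.2f; gestation %.2f; max lifespan %.0f\n",
              x$asm_female, x$asm_male, x$asm_pooled, x$gestation, x$max_lifespan))
  invisible(x)
}

valid_sexes   <- c("female", "male")
valid_sources <- c("bycatch", "single_stranding", "mass_stranding", "human_care")

#' Construct a methylation dataset
#'
#' The pipeline's universal input: a CpG-by-sample matrix of beta values
#' (methylation fractions in [0,1]), an optional parallel matrix of detection
#' p-values, and per-sample metadata. All invariants are checked here so that
#' downstream stages can assume a clean object.
#'
#' @param betas numeric matrix, rows = CpG probes, columns = samples;
#'   dimnames required (CpG ids, sample ids), values in [0,1].
#' @param samples data.frame of per-sample metadata with columns `sample_id`,
#'   `dental_age` (years), `age_is_minimum` (logical), `sex`
#'   ("female"/"male"), `dcc` (decomposition code, 1-3), `source`,
#'   `collection_year`; optional `storage_years`. Rows are joined to beta
#'   columns by `sample_id`, not by position.
#' @param detection_p optional numeric matrix of per-probe detection
#'   p-values, same dimensions and dimnames as `betas`.
#' @param life_history a [life_history_params()] object; `max_lifespan`
#'   bounds `dental_age`.
#' @param analysis_year calendar year of methylation analysis; used to fill
#'   `storage_years` as `analysis_year - collection_year` when absent.
#' @return an object of class `methylation_dataset` with elements `betas`,
#'   `detection_p`, `samples`, `cpg_ids`, `sample_ids`.
#' @export
methylation_dataset <- function(betas, samples, detection_p = NULL,
                                life_history = life_history_params(),
                                analysis_year = 2023) {
  if (!is.matrix(betas) || !is.numeric(betas)) stop("betas must be a numeric matrix")
  cpg_ids <- rownames(betas)
  sample_ids <- colnames(betas)
  if (is.null(cpg_ids) || is.null(sample_ids)) {
    stop("betas must carry CpG row names and sample column names")
  }
  if (anyDuplicated(cpg_ids)) {
    stop("duplicate CpG ids: ", paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(betas) | betas < 0 | betas > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta values outside [0,1] or non-finite at [",
         paste(sprintf("%s,%s", cpg_ids[bad[, 1]], sample_ids[bad[, 2]])[
           seq_len(min(5, nrow(bad)))], collapse = "; "), "]")
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(betas))) {
      stop("detection_p must have the same dimensions as betas")
    }
    if (is.null(dimnames(detection_p))) dimnames(detection_p) <- dimnames(betas)
    if (!identical(rownames(detection_p), cpg_ids) ||
        !identical(colnames(detection_p), sample_ids)) {
      stop("detection_p dimnames must match betas")
    }
    if (any(!is.finite(detection_p) | detection_p < 0 | detection_p > 1)) {
      stop("detection p-values must be finite and within [0,1]")
    }
  }
  samples <- validate_sample_sheet(samples, life_history, analysis_year)
  missing_meta <- setdiff(sample_ids, samples$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples missing from sheet: ", paste(missing_meta, collapse = ", "))
  }
  extra_meta <- setdiff(samples$sample_id, sample_ids)
  if (length(extra_meta) > 0) {
    stop("sheet samples absent from beta matrix: ", paste(extra_meta, collapse = ", "))
  }
  # align metadata to beta column order; the join is by id, never position
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(betas = betas, detection_p = detection_p, samples = samples,
                 cpg_ids = cpg_ids, sample_ids = sample_ids,
                 life_history = life_history),
            class = "methylation_dataset")
}

validate_sample_sheet <- function(samples, life_history, analysis_year) {
  req <- c("sample_id", "dental_age", "age_is_minimum", "sex", "dcc",
           "source", "collection_year")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  samples$age_is_minimum <- as.logical(samples$age_is_minimum)
  if (any(!is.finite(samples$dental_age)) || any(samples$dental_age < 0)) {
    stop("dental_age must be finite and >= 0")
  }
  if (any(samples$dental_age > life_history$max_lifespan)) {
    stop("dental_age exceeds configured maximum lifespan (",
         life_history$max_lifespan, " y)")
  }
  if (!all(samples$sex %in% valid_sexes)) {
    stop("sex must be one of: ", paste(valid_sexes, collapse = ", "))
  }
  if (!all(samples$dcc %in% c(1L, 2L, 3L))) {
    bad <- unique(samples$dcc[!samples$dcc %in% c(1L, 2L, 3L)])
    stop("dcc outside {1,2,3}: ", paste(bad, collapse = ", "))
  }
  if (!all(samples$source %in% valid_sources)) {
    stop("source must be one of: ", paste(valid_sources, collapse = ", "))
  }
  if (is.null(samples$storage_years)) {
    samples$storage_years <- analysis_year - samples$collection_year
  }
  if (any(samples$storage_years < 0)) stop("storage_years must be >= 0")
  samples
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d CpGs x %d samples%s\n",
              length(x$cpg_ids), length(x$sample_ids),
              if (is.null(x$detection_p)) " (no detection p-values)" else ""))
  cat(sprintf("  ages %.1f-%.1f y; %d female / %d male\n",
              min(x$samples$dental_age), max(x$samples$dental_age),
              sum(x$samples$sex == "female"), sum(x$samples$sex == "male")))
  invisible(x)
}

#' Number of samples / CpGs in a dataset
#' @param dataset a `methylation_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' @rdname n_samples
#' @export
n_cpgs <- function(dataset) length(dataset$cpg_ids)

#' Restrict a dataset to a set of samples
#'
#' @param dataset a `methylation_dataset`.
#' @param sample_ids character ids to keep, in the order given.
#' @return the restricted `methylation_dataset`.
#' @export
subset_samples <- function(dataset, sample_ids) {
  unknown <- setdiff(sample_ids, dataset$sample_ids)
  if (length(unknown) > 0) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  if (length(sample_ids) == 0) stop("cannot subset to an empty dataset")
  methylation_dataset(
    betas = dataset$betas[, sample_ids, drop = FALSE],
    samples = dataset$samples[match(sample_ids, dataset$samples$sample_id), , drop = FALSE],
    detection_p = if (!is.null(dataset$detection_p))
      dataset$detection_p[, sample_ids, drop = FALSE] else NULL,
    life_history = dataset$life_history)
}

# ---- CSV I/O ---------------------------------------------------------------

read_matrix_csv <- function(path, id_col = "cpg_id", transposed = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix CSV needs an id column plus >= 1 data column: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric cell(s) in ", path, " near row ", bad[1, 1], ", column ",
         colnames(df)[-1][bad[1, 2]])
  }
  rownames(m) <- ids
  if (transposed) m <- t(m)
  m
}

write_matrix_csv <- function(m, path, id_col = "cpg_id") {
  txt <- apply(m, 2, format_double)
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), txt, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a methylation dataset from CSV files
#'
#' Reads a beta-value matrix (rows = CpG probes, first column = CpG id,
#' remaining columns = samples — the usual methylation-array export layout),
#' an optional detection p-value matrix of identical layout, and a sample
#' sheet, joins them by sample id and validates the result.
#'
#' @param beta_path path to the beta CSV.
#' @param sheet_path path to the sample sheet CSV.
#' @param detection_p_path optional path to the detection p-value CSV.
#' @param transposed set `TRUE` if the matrix CSVs have samples as rows.
#' @param life_history,analysis_year passed to [methylation_dataset()].
#' @return a validated `methylation_dataset`; the beta file's column order is
#'   preserved.
#' @export
load_dataset <- function(beta_path, sheet_path, detection_p_path = NULL,
                         transposed = FALSE,
                         life_history = life_history_params(),
                         analysis_year = 2023) {
  for (p in c(beta_path, sheet_path, detection_p_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  betas <- read_matrix_csv(beta_path, transposed = transposed)
  sheet <- utils::read.csv(sheet_path, check.names = FALSE, stringsAsFactors = FALSE)
  detp <- if (!is.null(detection_p_path)) {
    read_matrix_csv(detection_p_path, transposed = transposed)
  }
  methylation_dataset(betas, sheet, detection_p = detp,
                      life_history = life_history, analysis_year = analysis_year)
}

#' Write a methylation dataset to CSV files
#'
#' Inverse of [load_dataset()]. Numbers are written with enough significant
#' digits that a load/save round trip reproduces every double bit-for-bit.
#'
#' @param dataset a `methylation_dataset`.
#' @param beta_path,sheet_path,detection_p_path output paths; the detection
#'   matrix is written only when present in the dataset.
#' @return the paths, invisibly.
#' @export
write_dataset <- function(dataset, beta_path, sheet_path, detection_p_path = NULL) {
  write_matrix_csv(dataset$betas, beta_path)
  utils::write.csv(dataset$samples, sheet_path, row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$detection_p) && !is.null(detection_p_path)) {
    write_matrix_csv(dataset$detection_p, detection_p_path)
  }
  invisible(c(beta_path, sheet_path, detection_p_path))
}

# ---- clock model type ------------------------------------------------------

#' Construct a fitted clock model
#'
#' A sparse linear predictor on the transformed-age scale: prediction in
#' years = `llin2_inverse(intercept + sum(coefficients * betas))`.
#' Usually produced by [fit_clock()]; the constructor is exported so models
#' can be rebuilt from serialized coefficients.
#'
#' @param alpha elastic-net mixing parameter in [0,1].
#' @param lambda penalty strength (> 0).
#' @param intercept intercept on the transformed-age scale.
#' @param coefficients named numeric vector, CpG id -> coefficient; only
#'   nonzero entries are kept.
#' @param life_history a [life_history_params()] object.
#' @param n_train training-set size.
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(alpha, lambda, intercept, coefficients,
                        life_history = life_history_params(), n_train = NA_integer_) {
  stopifnot(alpha >= 0, alpha <= 1, lambda > 0, is.finite(intercept))
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    stop("coefficients must be named by CpG id")
  }
  structure(list(alpha = alpha, lambda = lambda, intercept = intercept,
                 coefficients = coefficients, life_history = life_history,
                 n_train = as.integer(n_train)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model: alpha %.2f, lambda %.4g, %d retained CpGs (n_train = %d)\n",
              x$alpha, x$lambda, length(x$coefficients), x$n_train))
  invisible(x)
}

#' Number of CpGs retained (nonzero coefficients) by a clock
#' @param model a `clock_model`.
#' @return integer count of nonzero coefficients.
#' @export
n_retained_cpgs <- function(model) length(model$coefficients)

clock_schema_version <- "1.0"

#' Save / load a clock model as JSON
#'
#' The file stores alpha, lambda, the intercept, the life-history anchors and
#' the CpG-to-coefficient table at full double precision, plus a schema
#' version; `load_clock(save_clock(m))` restores every field exactly.
#'
#' @param model a `clock_model`.
#' @param path output (input) JSON path.
#' @return `save_clock` returns `path` invisibly; `load_clock` a `clock_model`.
#' @export
save_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  # numbers are stored as 17-significant-digit strings: JSON writers round
  # doubles, and the contract here is an exact decimal round-trip
  obj <- list(schema_version = clock_schema_version,
              alpha = format_double(model$alpha),
              lambda = format_double(model$lambda),
              intercept = format_double(model$intercept),
              life_history = lapply(unclass(model$life_history), format_double),
              n_train = if (!is.na(model$n_train)) model$n_train,
              cpg_ids = names(model$coefficients),
              coefficients = format_double(unname(model$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_clock
#' @export
load_clock <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed clock file ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) || obj$schema_version != clock_schema_version) {
    stop("clock file ", path, " has schema version '",
         obj$schema_version %||% "<none>", "', expected '", clock_schema_version, "'")
  }
  coefs <- as.numeric(obj$coefficients %||% numeric(0))
  names(coefs) <- as.character(obj$cpg_ids %||% character(0))
  clock_model(alpha = as.numeric(obj$alpha), lambda = as.numeric(obj$lambda),
              intercept = as.numeric(obj$intercept),
              coefficients = coefs,
              life_history = do.call(life_history_params,
                                     lapply(as.list(obj$life_history), as.numeric)),
              n_train = obj$n_train %||% NA_integer_)
}
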
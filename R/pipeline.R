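#' Assemble and validate a pipeline configuration
#'
#' A single configuration object drives [run_pipeline()]. It can be built
#' from named arguments, from a YAML file, or both (arguments override file
#' entries). Every run must carry an explicit seed — there are no unseeded
#' analyses.
#'
#' @param ... configuration entries (see Details).
#' @param file optional YAML file of configuration entries.
#'
#' @details Recognised entries: `betas`, `sheet`, `detection_p` (paths),
#' `out_dir`, `seed`, `analysis_year` (default 2023), `life_history` (list
#' passed to [life_history_params()]), `manual_exclusions` (sample ids),
#' `qc` (`p_threshold`, `max_fraction`, `sd_threshold`), `alpha` (numeric,
#' or `"auto"` to select per subset via [select_alpha()]), `alpha_search`
#' (`grid`, `n_subsets`, `train_fraction`), `error_cutoff` (restricted-subset
#' rule, default 6), `subsets` (default relaxed/strict/restricted), `hybrid`
#' (`run`, `k`, `n_trees`, `min_mature`), `sex` (`run`, `alpha`).
#'
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- if (!is.null(file)) yaml::read_yaml(file) else list()
  override <- list(...)
  cfg[names(override)] <- override
  defaults <- list(analysis_year = 2023, manual_exclusions = character(0),
                   qc = list(), alpha = "auto",
                   alpha_search = list(grid = seq(0, 1, by = 0.1),
                                       n_subsets = 20, train_fraction = 2 / 3),
                   error_cutoff = 6,
                   subsets = c("relaxed", "strict", "restricted"),
                   hybrid = list(run = TRUE, k = 5, n_trees = 1000, min_mature = 10),
                   sex = list(run = TRUE, alpha = 0.4))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(cfg[[nm]]))
      cfg[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  for (req in c("betas", "sheet", "out_dir", "seed")) {
    if (is.null(cfg[[req]])) stop("pipeline config missing required entry '", req, "'")
  }
  for (p in c(cfg$betas, cfg$sheet, cfg$detection_p)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$life_history <- do.call(life_history_params, as.list(cfg$life_history %||% list()))
  if (!identical(cfg$alpha, "auto")) {
    stopifnot(is.numeric(cfg$alpha), cfg$alpha >= 0, cfg$alpha <= 1)
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_pred_csv <- function(pred, path) {
  out <- pred
  for (col in names(out)) if (is.numeric(out[[col]])) out[[col]] <- format_double(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Run the full clock analysis pipeline
#'
#' Orchestrates: data loading, sample QC, relaxed-subset alpha selection and
#' LOOCV, subset construction, per-subset clock fitting / LOOCV / error
#' metrics, hybrid-model cross-validation, sex classification, and the
#' decomposition / storage covariate tests. All artifacts are written under
#' `config$out_dir`; a manifest records the configuration, seed and artifact
#' list. Re-running with an identical configuration and seed reproduces
#' every numeric output exactly.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
    artifacts <<- c(artifacts, name)
    path
  }

  dataset <- stage("load", load_dataset(
    config$betas, config$sheet, detection_p_path = config$detection_p,
    life_history = config$life_history, analysis_year = config$analysis_year))

  qc <- stage("qc", do.call(qc_report, c(
    list(dataset = dataset, manual_exclusions = config$manual_exclusions),
    config$qc)))
  emit(list(failed_probe_fraction = as.list(qc$failed_probe_fraction),
            fraction_outliers = qc$fraction_outliers,
            multivariate_outliers = qc$multivariate_outliers,
            excluded = qc$excluded, retained = qc$retained), "qc.json")
  clean <- stage("qc", apply_qc(dataset, qc))

  pick_alpha <- function(ds, key) {
    if (!identical(config$alpha, "auto")) return(config$alpha)
    search <- select_alpha(ds, grid = config$alpha_search$grid,
                           n_subsets = config$alpha_search$n_subsets,
                           train_fraction = config$alpha_search$train_fraction,
                           seed = derive_seed(seed, paste0("alpha:", key)))
    search$selected_alpha
  }

  relaxed_alpha <- stage("alpha_relaxed", pick_alpha(clean, "relaxed"))
  relaxed_loocv <- stage("loocv_relaxed", loocv_predict(
    clean, alpha = relaxed_alpha, seed = derive_seed(seed, "loocv:relaxed")))

  subsets <- stage("subsets", build_subsets(clean, relaxed_loocv,
                                            error_cutoff = config$error_cutoff))
  emit(subsets, "subsets.json")

  results <- list()
  for (nm in config$subsets) {
    ds <- subset_samples(clean, subsets[[nm]])
    alpha <- if (nm == "relaxed") relaxed_alpha else
      stage(paste0("alpha_", nm), pick_alpha(ds, nm))
    loocv <- if (nm == "relaxed") relaxed_loocv else
      stage(paste0("loocv_", nm),
            loocv_predict(ds, alpha = alpha,
                          seed = derive_seed(seed, paste0("loocv:", nm))))
    model <- stage(paste0("fit_", nm),
                   fit_clock(ds, alpha = alpha,
                             seed = derive_seed(seed, paste0("fit:", nm))))
    save_clock(model, file.path(out, paste0("clock_", nm, ".json")))
    artifacts <- c(artifacts, paste0("clock_", nm, ".json"))
    write_pred_csv(loocv, file.path(out, paste0("loocv_", nm, ".csv")))
    artifacts <- c(artifacts, paste0("loocv_", nm, ".csv"))
    ev <- stage(paste0("eval_", nm), evaluate_predictions(loocv))
    emit(c(list(subset = nm, alpha = alpha,
                n_retained_cpgs = n_retained_cpgs(model)), unclass(ev)),
         paste0("eval_", nm, ".json"))
    results[[nm]] <- list(alpha = alpha, loocv = loocv, eval = ev, model = model)
  }

  if (isTRUE(config$hybrid$run)) {
    hybrid_cv <- stage("hybrid", cross_validate_hybrid(
      clean, k = config$hybrid$k, seed = derive_seed(seed, "hybrid"),
      n_trees = config$hybrid$n_trees, min_mature = config$hybrid$min_mature))
    write_pred_csv(hybrid_cv, file.path(out, "hybrid_cv.csv"))
    artifacts <- c(artifacts, "hybrid_cv.csv")
    emit(unclass(stage("hybrid", evaluate_predictions(hybrid_cv))),
         "eval_hybrid.json")
    results$hybrid <- list(cv = hybrid_cv)
  }

  if (isTRUE(config$sex$run)) {
    sex_model <- stage("sex", fit_sex(clean, alpha = config$sex$alpha,
                                      seed = derive_seed(seed, "sex")))
    sex_pred <- stage("sex", predict_sex(sex_model, clean))
    write_pred_csv(sex_pred, file.path(out, "sex_pred.csv"))
    artifacts <- c(artifacts, "sex_pred.csv")
    results$sex <- list(model = sex_model, pred = sex_pred)
  }

  cov <- stage("covariates", {
    err <- relaxed_loocv$abs_error
    list(decomposition = unclass(decomposition_effect(err, clean$samples$dcc)),
         storage = unclass(storage_effect(err, clean$samples$storage_years,
                                          clean$samples$dental_age)))
  })
  cov$decomposition$group_sizes <- as.list(cov$decomposition$group_sizes)
  emit(cov, "covariates.json")

  artifacts <- c(artifacts, "manifest.json")
  manifest <- list(seed = seed,
                   analysis_year = config$analysis_year,
                   alpha = config$alpha,
                   n_samples_loaded = n_samples(dataset),
                   n_samples_retained = n_samples(clean),
                   subset_sizes = lapply(subsets, length),
                   artifacts = artifacts,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(results, list(manifest = manifest, qc = qc, subsets = subsets)))
}
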
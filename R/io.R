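# CSV interchange for cohorts and results.  All tables are plain CSV; trait
# columns keep their instrument names (with hyphens), so readers use
# check.names = FALSE.

#' Write a cohort to CSV files
#'
#' Writes `trials.csv` (long, both tasks; unused fields empty),
#' `traits.csv` and, when present, `ground_truth.csv` into `dir`.
#'
#' @param cohort Cohort list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             traits = file.path(dir, "traits.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(cohort$trials, paths["trials"], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$traits, paths["traits"], row.names = FALSE,
                   na = "")
  if (!is.null(cohort$ground_truth))
    utils::write.csv(cohort$ground_truth, paths["ground_truth"],
                     row.names = FALSE, na = "")
  else paths <- paths[c("trials", "traits")]
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort_csv()]; round-trips a written cohort exactly
#' (up to the numeric formatting used by the writer).
#'
#' @param dir Directory containing `trials.csv`, `traits.csv` and
#'   optionally `ground_truth.csv`.
#' @return Cohort list with `trials`, `traits` and (if present)
#'   `ground_truth`.
#' @export
read_cohort_csv <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = "")
  trials$is_attention_check <- as.logical(trials$is_attention_check)
  trials$missed <- as.logical(trials$missed)
  traits <- utils::read.csv(file.path(dir, "traits.csv"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  out <- list(trials = trials, traits = traits)
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    gt <- utils::read.csv(gt_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if ("careless" %in% names(gt)) gt$careless <- as.logical(gt$careless)
    out$ground_truth <- gt
  }
  out
}

#' Default run configuration
#'
#' All tunable parameters of a pipeline run with their defaults: the
#' cohort emulates a 325-participant online sample with a planted latent
#' affective factor (target first canonical correlation 0.37), mean
#' hyperaltruism shift 0.08 and mean prosocial-apathy shift 0.09, a 2
#' percent baseline missed-trial rate, and a 5 percent fraction of
#' careless participants (attention-check fail probability 1/2, 15 percent
#' missed trials) for the exclusion stage to catch.
#'
#' @param ... Named overrides of any default field.
#' @return Named list (class `prosocca_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n = 325L,
    r_target = 0.37,
    loadings = as.list(default_trait_loadings()),
    delta_kappa = 0.08,
    delta_lambda = 0.09,
    hyper_sd = 0.15,
    apathy_sd = 0.08,
    n_harm_regular = 35L,
    n_harm_checks = 2L,
    miss_rate = 0.02,
    careless_frac = 0.05,
    careless_miss_rate = 0.15,
    n_starts = 10L,
    n_perm = 1000L,
    loading_threshold = 0.3,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "prosocca_config")
}

validate_config <- function(config) {
  if (!inherits(config, "prosocca_config")) config <- do.call(default_config, config)
  if (is.null(config$n) || config$n < 1) stop("config: n must be >= 1")
  if (config$miss_rate < 0 || config$miss_rate >= 1)
    stop("config: miss_rate must lie in [0, 1)")
  config$loadings <- stats::setNames(unlist(config$loadings),
                                     names(config$loadings) %||% trait_names())
  config
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`; fields override
#'   the defaults of [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml"))
  validate_config(do.call(default_config, raw))
}
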
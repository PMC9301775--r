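#' Simulate a cohort and write it to disk
#'
#' Generator stage of the pipeline: builds the synthetic cohort defined by
#' the configuration and writes `trials.csv`, `traits.csv`,
#' `ground_truth.csv` plus a JSON manifest (configuration, seed, row
#' counts) to the output directory.
#'
#' @param config Configuration from [default_config()] or [read_config()];
#'   `out_dir` must be set.
#' @return Invisibly, the cohort list.
#' @export
run_simulate <- function(config = default_config()) {
  config <- validate_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir must be set")
  cohort <- simulate_cohort(config)
  paths <- write_cohort_csv(cohort, config$out_dir)
  manifest <- list(
    stage = "simulate",
    config = unclass(config),
    rows = list(trials = nrow(cohort$trials), traits = nrow(cohort$traits),
                ground_truth = nrow(cohort$ground_truth)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(cohort)
}

#' Fit both choice models to every participant in a cohort
#'
#' @param trials Long trial table (both tasks) for one or more participants.
#' @param n_starts Random restarts per fit.
#' @param seed Base seed; each participant's fits are seeded
#'   deterministically from it.
#' @return Data frame with one row per participant: harm parameters
#'   (`kappa_self`, `kappa_other`, `beta_self`, `beta_other`, `harm_nll`,
#'   `harm_converged`), effort parameters (`lambda_self`, `lambda_other`,
#'   `beta_effort`, `effort_nll`, `n_missed`, `effort_converged`) and the
#'   derived indices `hyperaltruism` and `prosocial_effort`.
#' @export
fit_cohort <- function(trials, n_starts = 10, seed = 1L) {
  ids <- sort(unique(trials$participant_id))
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    ht <- trials[trials$participant_id == id & trials$task == "harm", ]
    et <- trials[trials$participant_id == id & trials$task == "effort", ]
    hf <- fit_harm_model(ht, n_starts = n_starts,
                         seed = (seed + 7L * i) %% .Machine$integer.max)
    ef <- fit_effort_model(et, n_starts = n_starts,
                           seed = (seed + 7L * i + 3L) %% .Machine$integer.max)
    data.frame(
      participant_id = id,
      kappa_self = hf$kappa_self, kappa_other = hf$kappa_other,
      beta_self = hf$beta_self, beta_other = hf$beta_other,
      harm_nll = hf$nll, harm_converged = hf$converged,
      lambda_self = ef$lambda_self, lambda_other = ef$lambda_other,
      beta_effort = ef$beta, effort_nll = ef$nll,
      n_missed = ef$n_missed, effort_converged = ef$converged,
      hyperaltruism = hyperaltruism(hf),
      prosocial_effort = prosocial_effort(ef),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage: simulate the cohort, apply exclusions, fit
#' both choice models per participant, derive the prosociality indices,
#' run the univariate behavioral statistics (Wilcoxon signed-rank tests on
#' the self/other parameters, Spearman correlations across tasks, the
#' Fisher r-to-z comparison of correlation magnitudes, repeated-measures
#' ANOVAs on work proportions), and relate the 18 traits to the 2 indices
#' by CCA with permutation inference, role classification and commonality
#' partitioning.  Stage timings and exclusion counts are logged to stderr
#' unless `quiet`.
#'
#' @param config Configuration from [default_config()] or [read_config()].
#' @param quiet Suppress stage logging (default `FALSE`).
#' @return List of class `prosocca_run`: `qc`, `params` (fitted parameters
#'   + indices), `stats` (one row per univariate test), `anova_effort`,
#'   `anova_reward`, `cca` (a `cca_result`), `cca_functions` (functions
#'   table with permutation p for function 1), `roles` (trait role
#'   classification, function 1), `commonality`, `n_retained`, `config`.
#'   If `config$out_dir` is set, all tables are also written as CSV with a
#'   JSON manifest.
#' @export
run_full <- function(config = default_config(), quiet = FALSE) {
  config <- validate_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("simulate", simulate_cohort(config))
  qcres <- stage("qc", apply_exclusions(cohort))
  say("[qc] excluded %d of %d participants",
      sum(qcres$qc$excluded), nrow(qcres$qc))
  kept <- qcres$cohort
  params <- stage("fit", fit_cohort(kept$trials, n_starts = config$n_starts,
                                    seed = config$seed + 11L))

  stats_tab <- stage("stats", {
    w_kappa <- wilcoxon_signed_rank(params$kappa_other, params$kappa_self)
    w_lambda <- wilcoxon_signed_rank(params$lambda_other, params$lambda_self)
    s_idx <- spearman_correlation(params$hyperaltruism,
                                  params$prosocial_effort)
    s_other <- spearman_correlation(params$kappa_other, -params$lambda_other)
    s_self <- spearman_correlation(params$kappa_self, params$lambda_self)
    n <- nrow(params)
    fz_idx_self <- fisher_z_difference(s_idx$statistic, n,
                                       s_self$statistic, n)
    fz_other_self <- fisher_z_difference(s_other$statistic, n,
                                         s_self$statistic, n)
    tab <- rbind(w_kappa, w_lambda, s_idx, s_other, s_self,
                 fz_idx_self, fz_other_self)
    tab$name <- c("wilcoxon_kappa_other_vs_self",
                  "wilcoxon_lambda_other_vs_self",
                  "spearman_hyperaltruism_prosocial_effort",
                  "spearman_kappa_other_lambda_other_rev",
                  "spearman_kappa_self_lambda_self",
                  "fisherz_indices_vs_self",
                  "fisherz_other_vs_self")
    tab
  })

  eff_trials <- kept$trials[kept$trials$task == "effort", ]
  anova_effort <- stage("anova_effort",
    rm_anova_2way(work_proportions(eff_trials, "effort_level"),
                  "effort_level"))
  anova_reward <- stage("anova_reward",
    rm_anova_2way(work_proportions(eff_trials, "reward"), "reward"))

  cca_out <- stage("cca", {
    X <- as.matrix(kept$traits[, trait_names()])
    Y <- cbind(hyperaltruism = params$hyperaltruism,
               prosocial_effort = params$prosocial_effort)
    cca <- fit_cca(X, Y)
    perm <- cca_permutation_test(X, Y, n_perm = config$n_perm,
                                 seed = config$seed + 13L)
    fn <- cca$significance
    fn$perm_p <- c(perm$p, rep(NA_real_, nrow(fn) - 1))
    thr <- config$loading_threshold
    roles <- classify_cca_roles(cca$x_loadings[, 1], cca$x_weights[, 1],
                                cca$x_cross[, 1], threshold = thr)
    sel <- roles$variable[abs(roles$loading) >= thr |
                            abs(roles$weight) >= thr]
    common <- if (length(sel) >= 2 && length(sel) <= 20)
      commonality_analysis(X[, sel, drop = FALSE], cca$y_scores[, 1])
    else NULL
    list(cca = cca, functions = fn, roles = roles, commonality = common)
  })

  out <- structure(list(
    qc = qcres$qc, params = params, stats = stats_tab,
    anova_effort = anova_effort, anova_reward = anova_reward,
    cca = cca_out$cca, cca_functions = cca_out$functions,
    roles = cca_out$roles, commonality = cca_out$commonality,
    n_retained = nrow(params), config = config,
    ground_truth = cohort$ground_truth
  ), class = "prosocca_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) if (!is.null(df))
      utils::write.csv(df, file.path(config$out_dir, nm), row.names = FALSE)
    wr(out$qc, "qc.csv"); wr(out$params, "params.csv")
    wr(out$stats, "stats.csv")
    wr(out$anova_effort, "anova_effort.csv")
    wr(out$anova_reward, "anova_reward.csv")
    wr(out$cca_functions, "cca_functions.csv")
    wr(out$roles, "cca_roles.csv"); wr(out$commonality, "commonality.csv")
    manifest <- list(stage = "run_full", config = unclass(config),
                     n_retained = out$n_retained,
                     n_excluded = sum(out$qc$excluded))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}

#' @export
print.prosocca_run <- function(x, ...) {
  cat(sprintf("prosocca pipeline run: %d retained of %d participants\n",
              x$n_retained, nrow(x$qc)))
  cat("\nBehavioral statistics:\n")
  print(x$stats, row.names = FALSE, digits = 3)
  cat("\nCanonical functions:\n")
  print(x$cca_functions, row.names = FALSE, digits = 3)
  invisible(x)
}
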
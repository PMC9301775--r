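#' Names of the 18 trait variables
#'
#' The affective/psychiatric battery: general personality-disorder screen
#' (SAPAS), borderline screen (MSI-BPD), depression and anxiety (DASS-21),
#' four psychopathy facets (SRP-4: Interpersonal, Affective, Lifestyle,
#' Antisocial), three apathy domains (AMI: Behavioral Activation, Social
#' Motivation, Emotional Sensitivity), three alexithymia facets (TAS-20:
#' Difficulty Describing/Identifying Feelings, Externally Oriented
#' Thinking) and four empathy facets (IRI: Perspective Taking, Fantasy,
#' Empathic Concern, Personal Distress).
#'
#' @return Character vector of length 18.
#' @export
trait_names <- function() {
  c("SAPAS", "MSI-BPD", "DASS-Dep", "DASS-Anx",
    "SRP-I", "SRP-Aff", "SRP-L", "SRP-Ant",
    "AMI-BA", "AMI-SM", "AMI-ES",
    "TAS-DDF", "TAS-DIF", "TAS-EOT",
    "IRI-PT", "IRI-FT", "IRI-EC", "IRI-PD")
}

#' Default planted trait loadings on the latent affective factor
#'
#' Signed loadings of each trait on a single latent "affective engagement"
#' factor: empathic concern and perspective taking load positively;
#' emotional apathy, externally oriented thinking and the interpersonal and
#' affective psychopathy facets load negatively; the remaining twelve
#' traits carry only a residual near-zero loading.
#'
#' @return Named numeric vector of length 18 with values in (-1, 1).
#' @export
default_trait_loadings <- function() {
  l <- stats::setNames(rep(-0.05, 18), trait_names())
  l[c("IRI-FT", "IRI-PD")] <- 0.05
  # the six substantive loadings sit well above the 0.3 interpretation
  # cutoff even after attenuation by the factor-estimation step, so the
  # planted variables classify as contributors by design
  l["IRI-EC"] <- 0.60
  l["IRI-PT"] <- 0.55
  l["AMI-ES"] <- -0.60
  l["TAS-EOT"] <- -0.55
  l["SRP-Aff"] <- -0.55
  l["SRP-I"] <- -0.50
  l
}

# Plausible instrument-scale means/sds used to place the continuous trait
# scores on familiar questionnaire ranges (synthetic choices; downstream
# analyses z-score, so only the correlation structure matters).
default_trait_scales <- function() {
  m <- c(2.8, 3.2, 4.5, 3.3, 15.1, 13.9, 16.4, 11.5,
         8.9, 10.2, 9.5, 12.4, 14.8, 17.3, 17.8, 16.5, 19.6, 11.1)
  s <- c(1.9, 2.8, 4.8, 4.0, 5.3, 4.9, 5.5, 4.4,
         4.3, 4.6, 4.2, 4.6, 5.9, 4.4, 5.2, 5.8, 5.0, 5.2)
  data.frame(trait = trait_names(), mean = m, sd = s,
             stringsAsFactors = FALSE)
}

#' Describe the planted latent structure of a synthetic cohort
#'
#' Bundles the parameters that define how traits and prosociality indices
#' are tied together: per-trait signed loadings on a single latent factor,
#' the target first canonical correlation between the 18-trait set and the
#' 2-index set, the mean shifts of the hyperaltruism and prosocial-apathy
#' effects, and the dispersion of the indices.  The index loading `c`
#' needed to reach `r_target` is solved in closed form from the
#' single-factor model: with `s = sum(l^2/(1-l^2))` over trait loadings and
#' `u = 2c^2/(1-c^2)` over the two (equally loaded) indices, the population
#' first canonical correlation is `sqrt(s/(1+s) * u/(1+u))`.
#'
#' @param loadings Named numeric vector of 18 trait loadings in (-1, 1).
#' @param r_target Target population first canonical correlation (default
#'   0.37; 0 gives a null cohort with independent traits and indices).
#' @param delta_kappa Mean hyperaltruism shift, `kappa_other - kappa_self`
#'   (default 0.08).
#' @param delta_lambda Mean prosocial-apathy shift, `lambda_other -
#'   lambda_self` (default 0.09).
#' @param hyper_sd SD of the hyperaltruism index around its mean (default 0.15).
#' @param apathy_sd SD of the apathy difference around its mean (default 0.08).
#' @return Object of class `planted_structure`.
#' @export
planted_structure <- function(loadings = default_trait_loadings(),
                              r_target = 0.37,
                              delta_kappa = 0.08, delta_lambda = 0.09,
                              hyper_sd = 0.15, apathy_sd = 0.08) {
  if (length(loadings) != 18)
    stop("loadings must have length 18 (one per trait)")
  if (is.null(names(loadings))) names(loadings) <- trait_names()
  if (any(abs(loadings) >= 1)) stop("trait loadings must lie in (-1, 1)")
  if (r_target < 0 || r_target > 0.95)
    stop("infeasible r_target (must lie in [0, 0.95])")
  s <- sum(loadings^2 / (1 - loadings^2))
  if (r_target == 0) {
    c_idx <- 0
  } else {
    if (s == 0)
      stop("r_target > 0 is infeasible when all trait loadings are zero")
    r2x <- s / (1 + s)
    r2y <- r_target^2 / r2x
    if (r2y >= 0.95)
      stop(sprintf("infeasible r_target: requires index communality %.3f", r2y))
    u <- r2y / (1 - r2y)
    c_idx <- sqrt(u / (2 + u))
  }
  structure(list(loadings = loadings, r_target = r_target,
                 index_loading = c_idx,
                 delta_kappa = delta_kappa, delta_lambda = delta_lambda,
                 hyper_sd = hyper_sd, apathy_sd = apathy_sd),
            class = "planted_structure")
}

#' Generate a synthetic trait cohort with planted ground truth
#'
#' Draws `n` participants from the single-factor model described by a
#' [planted_structure()]: a latent factor `A ~ N(0, 1)`, 18 trait scores
#' `t_j = l_j A + sqrt(1 - l_j^2) e_j` rescaled to instrument-like ranges,
#' and standardized hyperaltruism/prosocial-effort indices loading equally
#' on `A`.  The indices are then mapped to choice-model parameters:
#' `kappa_other - kappa_self` centred on `delta_kappa` (kappas clipped to
#' \[0, 1\]) and `lambda_other - lambda_self` centred on `delta_lambda`
#' (lambdas clipped to \[0, 0.5\]), plus lognormal softmax temperatures.
#' The ground-truth table is never consumed by the fitting stages; it
#' exists to validate them.
#'
#' @param n Number of participants.
#' @param planted A [planted_structure()].
#' @param seed Integer seed.
#' @return List with `traits` (data frame: `participant_id` + 18 trait
#'   columns) and `ground_truth` (data frame: `participant_id`,
#'   `kappa_self`, `kappa_other`, `beta_self`, `beta_other`, `lambda_self`,
#'   `lambda_other`, `beta_effort`, `latent_A`, `hyperaltruism`,
#'   `prosocial_effort`).
#' @export
generate_trait_cohort <- function(n, planted = planted_structure(), seed = 1L) {
  stopifnot(inherits(planted, "planted_structure"), n >= 1)
  rng <- local_rng(seed)
  on.exit(rng$restore())

  A <- stats::rnorm(n)
  l <- planted$loadings
  Z <- sapply(seq_along(l), function(j)
    l[j] * A + sqrt(1 - l[j]^2) * stats::rnorm(n))
  scales <- default_trait_scales()
  traits_mat <- sweep(sweep(Z, 2, scales$sd, `*`), 2, scales$mean, `+`)
  traits <- data.frame(participant_id = seq_len(n), round(traits_mat, 4),
                       check.names = FALSE, stringsAsFactors = FALSE)
  names(traits) <- c("participant_id", trait_names())

  cc <- planted$index_loading
  hyper_star <- cc * A + sqrt(1 - cc^2) * stats::rnorm(n)
  pe_star <- cc * A + sqrt(1 - cc^2) * stats::rnorm(n)

  hyper_raw <- planted$delta_kappa + planted$hyper_sd * hyper_star
  apathy_raw <- planted$delta_lambda + planted$apathy_sd * (-pe_star)

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  kappa_self <- clip(stats::rnorm(n, 0.37, 0.15), 0, 1)
  kappa_other <- clip(kappa_self + hyper_raw, 0, 1)
  lambda_self <- clip(stats::rnorm(n, 0.02, 0.06), 0, 0.5)
  lambda_other <- clip(lambda_self + apathy_raw, 0, 0.5)
  beta_harm <- clip(exp(stats::rnorm(n, log(5), 0.4)), 0.5, 30)
  beta_effort <- clip(exp(stats::rnorm(n, log(2), 0.4)), 0.2, 20)

  ground_truth <- data.frame(
    participant_id = seq_len(n),
    kappa_self = kappa_self, kappa_other = kappa_other,
    beta_self = beta_harm, beta_other = beta_harm,
    lambda_self = lambda_self, lambda_other = lambda_other,
    beta_effort = beta_effort,
    latent_A = A,
    hyperaltruism = hyper_raw,
    prosocial_effort = -apathy_raw,
    stringsAsFactors = FALSE
  )
  list(traits = traits, ground_truth = ground_truth)
}

#' Simulate a complete synthetic cohort (traits + task choices)
#'
#' End-to-end generator: draws a trait cohort with planted ground truth,
#' builds one harm-aversion and one effort trial set shared by all
#' participants, and simulates every participant's choices from their true
#' parameters.  A configurable fraction of participants is "careless":
#' they fail attention checks with probability 1/2 and miss effort trials
#' at an elevated rate, so the quality-control stage has real work to do.
#'
#' @param config Run configuration from [default_config()].
#' @return List with `trials` (long data frame over participants and both
#'   tasks), `traits`, `ground_truth` (with added `careless` flag), and
#'   `config`.
#' @export
simulate_cohort <- function(config = default_config()) {
  config <- validate_config(config)
  n <- config$n
  planted <- planted_structure(
    loadings = config$loadings, r_target = config$r_target,
    delta_kappa = config$delta_kappa, delta_lambda = config$delta_lambda,
    hyper_sd = config$hyper_sd, apathy_sd = config$apathy_sd)
  cohort <- generate_trait_cohort(n, planted, seed = config$seed)
  gt <- cohort$ground_truth

  harm_trials <- generate_harm_trialset(
    n_regular_per_condition = config$n_harm_regular,
    n_checks_per_condition = config$n_harm_checks,
    seed = config$seed + 1L)
  effort_trials <- generate_effort_trialset()

  rng <- local_rng(config$seed + 2L)
  on.exit(rng$restore())
  careless <- stats::runif(n) < config$careless_frac
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2)

  per_part <- vector("list", n)
  for (i in seq_len(n)) {
    hp <- list(kappa_self = gt$kappa_self[i], kappa_other = gt$kappa_other[i],
               beta_self = gt$beta_self[i], beta_other = gt$beta_other[i])
    ep <- list(lambda_self = gt$lambda_self[i],
               lambda_other = gt$lambda_other[i], beta = gt$beta_effort[i])
    h <- simulate_harm_choices(
      hp, harm_trials, seed = seeds[i, 1],
      check_fail_prob = if (careless[i]) 0.5 else 0)
    e <- simulate_effort_choices(
      ep, effort_trials, seed = seeds[i, 2],
      miss_rate = if (careless[i]) config$careless_miss_rate else
        config$miss_rate)
    per_part[[i]] <- rbind(
      data.frame(participant_id = i, task = "harm", trial_id = h$trial_id,
                 beneficiary = h$beneficiary, d_money = h$d_money,
                 d_shocks = h$d_shocks, reward = NA_real_,
                 effort_level = NA_integer_,
                 is_attention_check = h$is_attention_check,
                 choice = h$choice, missed = h$missed,
                 stringsAsFactors = FALSE),
      data.frame(participant_id = i, task = "effort", trial_id = e$trial_id,
                 beneficiary = e$beneficiary, d_money = NA_real_,
                 d_shocks = NA_real_, reward = e$reward,
                 effort_level = e$effort_level,
                 is_attention_check = FALSE,
                 choice = e$choice, missed = e$missed,
                 stringsAsFactors = FALSE))
  }
  gt$careless <- careless
  list(trials = do.call(rbind, per_part), traits = cohort$traits,
       ground_truth = gt, config = config)
}
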
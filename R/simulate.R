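#' Simulate choices on the harm aversion task
#'
#' Draws a harmful/helpful choice on each trial from the softmax model
#' under known parameters.  On regular trials the choice is Bernoulli with
#' `P(harmful) = p_harmful(harm_delta_value(...), beta)` using the
#' condition's parameters.  On attention-check trials a compliant agent
#' always picks the dominant option (more money and fewer shocks); setting
#' `check_fail_prob > 0` simulates careless responding.
#'
#' @param params Named list/vector: `kappa_self`, `kappa_other`,
#'   `beta_self`, `beta_other`.
#' @param trials Trial set from [generate_harm_trialset()].
#' @param seed Integer seed.
#' @param check_fail_prob Probability of choosing the dominated option on
#'   each attention check (default 0: fully compliant).
#' @return The trial data frame with added columns `choice`
#'   (`"harmful"`/`"helpful"`) and `missed` (always `FALSE`; harm-task
#'   responses were not time-limited).
#' @export
simulate_harm_choices <- function(params, trials, seed = 1L,
                                  check_fail_prob = 0) {
  params <- as.list(params)
  if (any(trials$d_money == 0 & trials$d_shocks == 0))
    stop("degenerate trial with d_money = d_shocks = 0")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  other <- trials$beneficiary == "other"
  kappa <- ifelse(other, params$kappa_other, params$kappa_self)
  beta <- ifelse(other, params$beta_other, params$beta_self)
  p_harm <- p_harmful(harm_delta_value(trials$d_money, trials$d_shocks, kappa),
                      beta)
  # dominant option on checks: harmful iff it has more money AND fewer shocks
  harm_dominates <- trials$d_money > 0 & trials$d_shocks < 0
  u <- stats::runif(nrow(trials))
  choice <- ifelse(u < p_harm, "harmful", "helpful")
  chk <- trials$is_attention_check
  if (any(chk)) {
    fail <- stats::runif(sum(chk)) < check_fail_prob
    dominant <- ifelse(harm_dominates[chk], "harmful", "helpful")
    dominated <- ifelse(harm_dominates[chk], "helpful", "harmful")
    choice[chk] <- ifelse(fail, dominated, dominant)
  }
  trials$choice <- choice
  trials$missed <- FALSE
  trials
}

#' Simulate choices on the prosocial effort task
#'
#' Draws work/rest choices from the effort-discounting softmax under known
#' parameters, optionally flagging a random fraction of trials as missed
#' (no response within the decision window); missed trials have no choice.
#'
#' @param params Named list/vector: `lambda_self`, `lambda_other`, `beta`.
#' @param trials Trial set from [generate_effort_trialset()].
#' @param seed Integer seed.
#' @param miss_rate Per-trial probability of a missed response, in \[0, 1).
#' @return The trial data frame with added columns `choice`
#'   (`"work"`/`"rest"`, `NA` when missed) and `missed`.
#' @export
simulate_effort_choices <- function(params, trials, seed = 1L, miss_rate = 0) {
  params <- as.list(params)
  stopifnot(miss_rate >= 0, miss_rate < 1)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  lambda <- ifelse(trials$beneficiary == "other",
                   params$lambda_other, params$lambda_self)
  sv <- effort_subjective_value(trials$reward, trials$effort_units, lambda)
  pw <- p_work(sv, params$beta, trials$rest_reward %||% 1)
  choice <- ifelse(stats::runif(nrow(trials)) < pw, "work", "rest")
  missed <- stats::runif(nrow(trials)) < miss_rate
  choice[missed] <- NA_character_
  trials$choice <- choice
  trials$missed <- missed
  trials
}
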
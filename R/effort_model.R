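#' Subjective value of a work offer
#'
#' Parabolic effort discounting: `SV = R - lambda * E^2`, where `R` is the
#' reward on offer (credits), `E` the numeric effort coding and `lambda`
#' the discount rate.  At `lambda = 0` reward is not discounted; the cap of
#' 0.5 is the point beyond which every offer in the 48-trial design falls
#' below the 1-credit rest value, so larger values are behaviourally
#' indistinguishable.
#'
#' @param reward Reward of the work offer (credits).
#' @param effort_units Numeric effort coding (3, 5, 7, 9 in the standard set).
#' @param lambda Effort discount rate in \[0, 0.5\].
#' @return Subjective value in credits (vectorised).
#' @export
effort_subjective_value <- function(reward, effort_units, lambda) {
  if (any(lambda < 0 | lambda > 0.5)) stop("lambda must lie in [0, 0.5]")
  reward - lambda * effort_units^2
}

#' Softmax probability of choosing to work
#'
#' Work-versus-rest softmax `exp(beta*SV) / (exp(beta*rest) + exp(beta*SV))`
#' with the rest option worth 1 credit; equivalently a logistic in
#' `beta * (SV - 1)`.  The probability of resting is `1 - p_work(...)`.
#'
#' @param sv Subjective value of the work offer (credits).
#' @param beta Inverse temperature (> 0).
#' @param rest_reward Value of the rest option (default 1 credit).
#' @return Probability of choosing to work (vectorised, stable).
#' @export
p_work <- function(sv, beta, rest_reward = 1) {
  if (any(beta <= 0)) stop("beta must be positive")
  stats::plogis(beta * (sv - rest_reward))
}

#' Negative log-likelihood of effort-task choices
#'
#' Bernoulli log-likelihood of work/rest choices with condition-specific
#' discount rates (`lambda_self`, `lambda_other`) and a single shared
#' inverse temperature `beta`.  Missed trials (no response) carry no
#' likelihood and are excluded.
#'
#' @param params Named list or vector with `lambda_self`, `lambda_other`,
#'   `beta`.
#' @param records Data frame: `beneficiary`, `reward`, `effort_units`,
#'   `choice` (`"work"`/`"rest"`), `missed` (logical, optional).
#' @param prob_floor Lower floor on each choice probability (default 1e-12).
#' @return Negative log-likelihood in nats over non-missed trials.
#' @export
effort_nll <- function(params, records, prob_floor = 1e-12) {
  params <- as.list(params)
  keep <- !(records$missed %||% rep(FALSE, nrow(records)))
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("all trials missed; no likelihood")
  records <- ensure_effort_units(records)
  lambda <- ifelse(records$beneficiary == "other",
                   params$lambda_other, params$lambda_self)
  sv <- effort_subjective_value(records$reward, records$effort_units, lambda)
  pw <- p_work(sv, params$beta)
  p_obs <- ifelse(records$choice == "work", pw, 1 - pw)
  -sum(log(pmax(p_obs, prob_floor)))
}

#' Fit the effort-discounting model to one participant
#'
#' Bounded maximum-likelihood estimation of (`lambda_self`, `lambda_other`,
#' `beta`) by multi-start L-BFGS-B, with `beta` searched on a log scale.
#' The two discount rates apply to their own condition's trials; the single
#' temperature is shared, so the three parameters are optimised jointly.
#'
#' @param records Choice records as in [effort_nll()].
#' @param n_starts Number of random restarts (default 10).
#' @param seed Integer seed controlling the restart draws.
#' @param beta_bounds Search bounds for `beta` (default `c(0.01, 30)`).
#' @return Object of class `effort_fit`: `lambda_self`, `lambda_other`,
#'   `beta`, `nll`, `converged`, `n_missed`, `n_starts`.
#' @export
fit_effort_model <- function(records, n_starts = 10, seed = 1L,
                             beta_bounds = c(0.01, 30)) {
  missed <- records$missed %||% rep(FALSE, nrow(records))
  n_missed <- sum(missed)
  records <- ensure_effort_units(records[!missed, , drop = FALSE])
  for (cond in c("self", "other"))
    if (sum(records$beneficiary == cond) < 1L)
      stop("need at least one non-missed trial per condition")
  rng <- local_rng(seed)
  on.exit(rng$restore())

  y <- as.numeric(records$choice == "work")
  other <- records$beneficiary == "other"
  E2 <- records$effort_units^2
  R <- records$reward
  lb_lo <- log(beta_bounds[1]); lb_hi <- log(beta_bounds[2])

  nll_gr <- function(par) {
    lam <- ifelse(other, par[2], par[1])
    beta <- exp(par[3])
    x <- R - lam * E2 - 1
    p <- stats::plogis(beta * x)
    pobs <- pmax(ifelse(y == 1, p, 1 - p), 1e-12)
    val <- -sum(log(pobs))
    resid <- p - y
    g_ls <- sum(resid[!other] * beta * (-E2[!other]))
    g_lo <- sum(resid[other] * beta * (-E2[other]))
    g_logb <- sum(resid * beta * x)
    list(value = val, gradient = c(g_ls, g_lo, g_logb))
  }

  best <- NULL
  starts <- cbind(stats::runif(n_starts, 0, 0.5),
                  stats::runif(n_starts, 0, 0.5),
                  stats::runif(n_starts, lb_lo, lb_hi))
  for (i in seq_len(n_starts)) {
    res <- try(stats::optim(starts[i, ], fn = function(p) nll_gr(p)$value,
                            gr = function(p) nll_gr(p)$gradient,
                            method = "L-BFGS-B",
                            lower = c(0, 0, lb_lo), upper = c(0.5, 0.5, lb_hi)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    cand <- list(lambda_self = res$par[1], lambda_other = res$par[2],
                 beta = exp(res$par[3]), nll = res$value,
                 conv = res$convergence == 0)
    if (is.null(best) || cand$nll < best$nll - 1e-10 ||
        (abs(cand$nll - best$nll) <= 1e-10 &&
           cand$lambda_other < best$lambda_other))
      best <- cand
  }
  if (is.null(best))
    best <- list(lambda_self = NA_real_, lambda_other = NA_real_,
                 beta = NA_real_, nll = Inf, conv = FALSE)
  structure(list(
    lambda_self = best$lambda_self, lambda_other = best$lambda_other,
    beta = best$beta, nll = best$nll, converged = best$conv,
    n_missed = n_missed, n_starts = n_starts
  ), class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat("Effort-discounting model fit\n")
  cat(sprintf("  lambda_self = %.4f  lambda_other = %.4f  beta = %.3f\n",
              x$lambda_self, x$lambda_other, x$beta))
  cat(sprintf("  NLL = %.3f  converged = %s  missed trials excluded = %d\n",
              x$nll, x$converged, x$n_missed))
  invisible(x)
}

#' Prosocial effort index
#'
#' Reverse-coded prosocial apathy: `-(lambda_other - lambda_self)`.  Higher
#' values mean reward for another person is discounted less steeply by
#' effort, i.e. more prosocial willingness to work.
#'
#' @param params An `effort_fit`, or any list/vector with `lambda_self` and
#'   `lambda_other`.
#' @return Prosocial effort index in \[-0.5, 0.5\].
#' @export
prosocial_effort <- function(params) {
  params <- as.list(params)
  -(params$lambda_other - params$lambda_self)
}

# Long-format trial tables carry only effort_level (percent); recover the
# numeric model coding (tenths of the calibrated maximum) when needed.
ensure_effort_units <- function(records) {
  if (is.null(records$effort_units))
    records$effort_units <- records$effort_level / 10
  records
}
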
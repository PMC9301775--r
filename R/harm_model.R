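#' Value difference between harmful and helpful options
#'
#' The harm-aversion model scores each trial by
#' `dV = (1 - kappa) * d_money - kappa * d_shocks`: the money advantage of
#' the harmful option discounted against its shock cost, weighted by the
#' harm-aversion parameter `kappa`.  At `kappa = 0` any profit is accepted
#' regardless of shocks; as `kappa` approaches 1 the decider sacrifices
#' ever more money to avoid additional shocks.
#'
#' @param d_money Money difference, harmful minus helpful (currency units).
#' @param d_shocks Shock-count difference, harmful minus helpful.
#' @param kappa Harm aversion weight in \[0, 1\].
#' @return Value difference in currency-equivalent units (vectorised).
#' @export
harm_delta_value <- function(d_money, d_shocks, kappa) {
  if (any(kappa < 0 | kappa > 1)) stop("kappa must lie in [0, 1]")
  (1 - kappa) * d_money - kappa * d_shocks
}

#' Softmax probability of choosing the harmful option
#'
#' Maps a value difference to a choice probability through a logistic
#' (softmax) function `1 / (1 + exp(-beta * dV))`.  `beta` is an inverse
#' temperature: near 0 choices approach coin flips; near the upper bound of
#' 100 the curve approximates a step function.
#'
#' @param delta_v Value difference (harmful minus helpful).
#' @param beta Inverse temperature in \[0, 100\].
#' @return Probability of the harmful option (vectorised, numerically
#'   stable for extreme `beta * delta_v`).
#' @export
p_harmful <- function(delta_v, beta) {
  if (any(beta < 0 | beta > 100)) stop("beta must lie in [0, 100]")
  stats::plogis(beta * delta_v)
}

#' Negative log-likelihood of harm-task choices
#'
#' Bernoulli log-likelihood of observed harmful/helpful choices under
#' condition-specific parameters: self trials use (`kappa_self`,
#' `beta_self`), other trials (`kappa_other`, `beta_other`).  Attention
#' checks must be excluded before calling.  Per-choice probabilities are
#' floored at `prob_floor` so the result is always finite.
#'
#' @param params Named list or vector with `kappa_self`, `kappa_other`,
#'   `beta_self`, `beta_other`.
#' @param records Data frame of choice records: `beneficiary`, `d_money`,
#'   `d_shocks`, `choice` (`"harmful"`/`"helpful"`).
#' @param prob_floor Lower floor on each choice probability (default 1e-12).
#' @return Negative log-likelihood in nats.
#' @export
harm_nll <- function(params, records, prob_floor = 1e-12) {
  params <- as.list(params)
  if (nrow(records) == 0L) stop("empty record set")
  if (any(records$is_attention_check %||% FALSE))
    stop("attention-check trials must be excluded from the likelihood")
  other <- records$beneficiary == "other"
  kappa <- ifelse(other, params$kappa_other, params$kappa_self)
  beta <- ifelse(other, params$beta_other, params$beta_self)
  p_harm <- p_harmful(harm_delta_value(records$d_money, records$d_shocks, kappa),
                      beta)
  p_obs <- ifelse(records$choice == "harmful", p_harm, 1 - p_harm)
  -sum(log(pmax(p_obs, prob_floor)))
}

#' Fit the harm-aversion model to one participant
#'
#' Bounded maximum-likelihood estimation of (`kappa_self`, `beta_self`,
#' `kappa_other`, `beta_other`).  Because the parameters are
#' condition-specific, the likelihood separates over conditions and each
#' (`kappa`, `beta`) pair is optimised on its own trials with `n_starts`
#' random restarts (L-BFGS-B; `beta` on a log scale for stability).
#' Boundary estimates are retained and flagged, not censored.
#'
#' @param records Choice records as in [harm_nll()]; attention checks, if
#'   present, are dropped automatically.
#' @param n_starts Number of random restarts per condition (default 10).
#' @param seed Integer seed controlling the restart draws.
#' @param beta_bounds Search bounds for `beta` (default `c(1e-4, 100)`).
#' @return Object of class `harm_fit`: a list with `kappa_self`,
#'   `kappa_other`, `beta_self`, `beta_other`, `nll`, `converged`,
#'   `n_starts`, `at_bound` (logical, any kappa at 0 or 1).
#' @export
fit_harm_model <- function(records, n_starts = 10, seed = 1L,
                           beta_bounds = c(1e-4, 100)) {
  records <- records[!(records$is_attention_check %||% FALSE) &
                       !(records$missed %||% FALSE), , drop = FALSE]
  for (cond in c("self", "other"))
    if (sum(records$beneficiary == cond) < 1L)
      stop("need at least one regular trial per condition")
  rng <- local_rng(seed)
  on.exit(rng$restore())

  fit_cond <- function(cond) {
    rec <- records[records$beneficiary == cond, , drop = FALSE]
    y <- as.numeric(rec$choice == "harmful")
    m <- rec$d_money; s <- rec$d_shocks
    lb_lo <- log(beta_bounds[1]); lb_hi <- log(beta_bounds[2])
    nll_gr <- function(par) {
      kappa <- par[1]; beta <- exp(par[2])
      dv <- (1 - kappa) * m - kappa * s
      p <- stats::plogis(beta * dv)
      pobs <- pmax(ifelse(y == 1, p, 1 - p), 1e-12)
      val <- -sum(log(pobs))
      resid <- p - y                       # d(-loglik)/d(beta*dv)
      g_kappa <- sum(resid * beta * (-m - s))
      g_logb <- sum(resid * beta * dv)
      list(value = val, gradient = c(g_kappa, g_logb))
    }
    best <- NULL
    starts <- cbind(stats::runif(n_starts),
                    stats::runif(n_starts, lb_lo, lb_hi))
    for (i in seq_len(n_starts)) {
      res <- try(stats::optim(starts[i, ], fn = function(p) nll_gr(p)$value,
                              gr = function(p) nll_gr(p)$gradient,
                              method = "L-BFGS-B",
                              lower = c(0, lb_lo), upper = c(1, lb_hi)),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      cand <- list(kappa = res$par[1], beta = exp(res$par[2]),
                   nll = res$value, conv = res$convergence == 0)
      if (is.null(best) || cand$nll < best$nll - 1e-10 ||
          (abs(cand$nll - best$nll) <= 1e-10 && cand$kappa < best$kappa))
        best <- cand
    }
    if (is.null(best))
      best <- list(kappa = NA_real_, beta = NA_real_, nll = Inf, conv = FALSE)
    best
  }

  fs <- fit_cond("self"); fo <- fit_cond("other")
  structure(list(
    kappa_self = fs$kappa, kappa_other = fo$kappa,
    beta_self = fs$beta, beta_other = fo$beta,
    nll = fs$nll + fo$nll,
    converged = fs$conv && fo$conv,
    n_starts = n_starts,
    at_bound = isTRUE(any(c(fs$kappa, fo$kappa) %in% c(0, 1)))
  ), class = "harm_fit")
}

#' @export
print.harm_fit <- function(x, ...) {
  cat("Harm-aversion model fit\n")
  cat(sprintf("  kappa_self = %.3f  kappa_other = %.3f\n",
              x$kappa_self, x$kappa_other))
  cat(sprintf("  beta_self  = %.3f  beta_other  = %.3f\n",
              x$beta_self, x$beta_other))
  cat(sprintf("  NLL = %.3f  converged = %s%s\n", x$nll, x$converged,
              if (x$at_bound) "  [kappa at bound]" else ""))
  invisible(x)
}

#' Hyperaltruism index
#'
#' Difference in harm aversion for others versus oneself,
#' `kappa_other - kappa_self`.  Positive values mean the decider forgoes
#' more money to spare another person shocks than to spare themselves.
#'
#' @param params A `harm_fit`, or any list/vector with `kappa_self` and
#'   `kappa_other`.
#' @return Hyperaltruism index in \[-1, 1\].
#' @export
hyperaltruism <- function(params) {
  params <- as.list(params)
  params$kappa_other - params$kappa_self
}

`%||%` <- function(a, b) if (is.null(a)) b else a
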
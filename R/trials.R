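#' Generate a harm-aversion trial set
#'
#' Builds a money-versus-shocks choice set for the harm aversion task.  On
#' each regular trial a harmful option offers more money and more electric
#' shocks than a helpful option; the trial is summarised by the positive
#' differences `d_money` (harmful minus helpful money) and `d_shocks`
#' (harmful minus helpful shocks).  A participant with harm aversion
#' `kappa` is indifferent when `d_money / (d_money + d_shocks) == kappa`,
#' so the generator stratifies the implied indifference ratio across (0, 1)
#' to keep `kappa` identifiable over its whole range.  Attention-check
#' trials contain a dominated option (one option has both more money and
#' fewer shocks).
#'
#' @param n_regular_per_condition Number of regular (trade-off) trials per
#'   beneficiary condition.  The default, 35, gives the standard 70-trial set.
#' @param n_checks_per_condition Number of attention-check trials per
#'   condition (default 2, i.e. 4 checks in total).
#' @param money_range Numeric length-2: range of `d_money` in currency units.
#' @param shock_range Integer length-2: range of `d_shocks` (shock counts).
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return A data frame with columns `trial_id`, `beneficiary`
#'   (`"self"`/`"other"`), `d_money`, `d_shocks`, `is_attention_check`.
#'   Regular trials have `d_money > 0` and `d_shocks > 0`; checks have the
#'   two deltas with opposite signs.
#' @examples
#' trials <- generate_harm_trialset(seed = 1)
#' table(trials$beneficiary, trials$is_attention_check)
#' @export
generate_harm_trialset <- function(n_regular_per_condition = 35,
                                   n_checks_per_condition = 2,
                                   money_range = c(0.1, 10),
                                   shock_range = c(1L, 19L),
                                   seed = 1L) {
  stopifnot(n_regular_per_condition >= 1, n_checks_per_condition >= 0)
  if (diff(range(money_range)) <= 0 || diff(range(shock_range)) <= 0)
    stop("degenerate money_range or shock_range (zero width)")
  if (min(money_range) <= 0 || min(shock_range) <= 0)
    stop("money_range and shock_range must be positive")

  rng <- local_rng(seed)
  m_lo <- money_range[1]; m_hi <- money_range[2]
  s_lo <- as.integer(shock_range[1]); s_hi <- as.integer(shock_range[2])

  gen_condition <- function(beneficiary) {
    # stratified indifference ratios kappa* = d_money / (d_money + d_shocks);
    # the reachable ratio range is bounded by the delta ranges
    r_max <- m_hi / (m_hi + s_lo)
    r_lo <- 0.02
    r_hi <- r_max - 0.005
    k <- n_regular_per_condition
    edges <- seq(r_lo, r_hi, length.out = k + 1)
    target <- edges[-(k + 1)] + diff(edges) * stats::runif(k)
    d_money <- numeric(k); d_shocks <- integer(k)
    for (i in seq_len(k)) {
      r <- target[i]
      # feasible shock counts keeping d_money = r/(1-r)*d_shocks in range
      ratio <- r / (1 - r)
      s_feas <- seq.int(s_lo, s_hi)
      s_feas <- s_feas[ratio * s_feas >= m_lo & ratio * s_feas <= m_hi]
      if (length(s_feas) == 0L) s_feas <- if (ratio * s_lo > m_hi) s_lo else s_hi
      s <- if (length(s_feas) == 1L) s_feas else
        s_feas[1L + floor(stats::runif(1) * length(s_feas))]
      m <- round(ratio * s, 1)
      m <- min(max(m, m_lo), m_hi)
      d_money[i] <- m; d_shocks[i] <- s
    }
    data.frame(beneficiary = beneficiary, d_money = d_money,
               d_shocks = as.numeric(d_shocks), is_attention_check = FALSE,
               stringsAsFactors = FALSE)
  }

  gen_checks <- function(beneficiary) {
    n <- n_checks_per_condition
    if (n == 0L) return(NULL)
    # alternate which option dominates: d_money>0 & d_shocks<0 (harmful
    # dominates) vs d_money<0 & d_shocks>0 (helpful dominates)
    harm_dom <- rep(c(TRUE, FALSE), length.out = n)
    m <- round(stats::runif(n, 1, m_hi), 1)
    s <- as.numeric(sample.int(s_hi - s_lo + 1L, n, replace = TRUE) + s_lo - 1L)
    data.frame(beneficiary = beneficiary,
               d_money = ifelse(harm_dom, m, -m),
               d_shocks = ifelse(harm_dom, -s, s),
               is_attention_check = TRUE, stringsAsFactors = FALSE)
  }

  out <- rbind(gen_condition("self"), gen_checks("self"),
               gen_condition("other"), gen_checks("other"))
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  rng$restore()
  out
}

#' Generate the prosocial effort trial set
#'
#' Builds the fixed 48-trial work-versus-rest design: 2 beneficiary
#' conditions (self/other) fully crossed with 4 effort levels (30/50/70/90
#' percent of each participant's calibrated maximum) and 3 reward levels
#' (2-4 credits), 2 repeats per cell.  The rest option always pays 1 credit
#' for no effort.  Effort enters the discounting model through a numeric
#' coding `effort_units` of 3, 5, 7, 9 (tenths of the calibrated maximum),
#' the coding under which a discount rate at the 0.5 cap pushes every work
#' offer below the rest value.
#'
#' @return A data frame with 48 rows and columns `trial_id`, `beneficiary`,
#'   `reward` (credits), `effort_level` (percent), `effort_units`,
#'   `rest_reward` (always 1).
#' @examples
#' eff <- generate_effort_trialset()
#' with(eff, table(beneficiary, effort_level, reward))
#' @export
generate_effort_trialset <- function() {
  grid <- expand.grid(rep = 1:2, reward = 2:4,
                      effort_level = c(30L, 50L, 70L, 90L),
                      beneficiary = c("self", "other"),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    trial_id = seq_len(nrow(grid)),
    beneficiary = grid$beneficiary,
    reward = as.numeric(grid$reward),
    effort_level = grid$effort_level,
    effort_units = grid$effort_level / 10,
    rest_reward = 1,
    stringsAsFactors = FALSE
  )
  out
}

# Save and restore the global RNG state around seeded generation so that
# package functions do not clobber the caller's random stream.
local_rng <- function(seed) {
  seed <- as.integer(seed)  # force now: a lazily evaluated seed expression
                            # may itself consume the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  })
}
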
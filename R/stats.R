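#' Wilcoxon signed-rank test (normal approximation with tie correction)
#'
#' Paired two-sided signed-rank test as reported in the behavioral
#' literature: zero differences are dropped (Wilcoxon's rule), ranks of
#' absolute differences use average ranks for ties, and the z statistic is
#' the plain normal approximation `z = (W - n(n+1)/4) / sigma` with the
#' tie-corrected variance `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`, no
#' continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return Data frame row: `name`, `statistic` (z), `df1`, `df2` (NA),
#'   `p`, `effect_size` (NA), plus attribute `W` (signed-rank sum of
#'   positive differences) and `n_used`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  if (n < 5L) stop("need at least 5 nonzero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(name = "wilcoxon_signed_rank", statistic = z,
                    df1 = NA_real_, df2 = NA_real_, p = p,
                    effect_size = NA_real_, stringsAsFactors = FALSE)
  attr(out, "W") <- W
  attr(out, "n_used") <- n
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the asymptotic
#' t-approximation p-value (via [stats::cor.test()]).  Because it operates
#' on ranks, the estimate is invariant to any strictly monotone recoding of
#' either variable, so reverse-coded indices correlate identically up to
#' sign.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @return Data frame row: `name`, `statistic` (rho), `df1` (n - 2),
#'   `df2` (NA), `p`, `effect_size` (rho).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(name = "spearman", statistic = unname(ct$estimate),
             df1 = length(x) - 2, df2 = NA_real_, p = ct$p.value,
             effect_size = unname(ct$estimate), stringsAsFactors = FALSE)
}

#' Compare two independent correlations via Fisher's r-to-z
#'
#' Tests whether two correlation coefficients (absolute values, as when
#' comparing correlation magnitudes across variable pairs) differ:
#' `z = (atanh|r1| - atanh|r2|) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed
#' normal p.  The two correlations are treated as independent.
#'
#' @param r1,r2 Correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes (> 3).
#' @return Data frame row: `name`, `statistic` (z), `df1`, `df2` (NA),
#'   `p`, `effect_size` (NA).
#' @export
fisher_z_difference <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("n must exceed 3")
  z <- (atanh(abs(r1)) - atanh(abs(r2))) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  data.frame(name = "fisher_z_difference", statistic = z,
             df1 = NA_real_, df2 = NA_real_, p = 2 * stats::pnorm(-abs(z)),
             effect_size = NA_real_, stringsAsFactors = FALSE)
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for the effort task's proportion-of-work-choices
#' analyses: a 2-level beneficiary factor crossed with a multi-level effort
#' or reward factor, both within subjects.  Sphericity is handled by the
#' Greenhouse-Geisser estimator whenever a factor (or the interaction) has
#' three or more levels, yielding the fractional degrees of freedom
#' conventionally reported; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.  Fitting is delegated to
#' [car::Anova()] on a multivariate linear model.
#'
#' @param data Long data frame with one row per participant x cell:
#'   columns `participant_id`, `beneficiary`, a level column named by
#'   `level_col`, and the dependent variable `prop_work`.
#' @param level_col Name of the multi-level within factor column
#'   (e.g. `"effort_level"` or `"reward"`).
#' @return Data frame with one row per effect (`beneficiary`, level
#'   factor, interaction): `name`, `statistic` (F), `df1`, `df2`
#'   (GG-corrected, possibly fractional), `p`, `effect_size` (partial eta
#'   squared), and `gg_epsilon`.
#' @export
rm_anova_2way <- function(data, level_col = "effort_level") {
  req <- c("participant_id", "beneficiary", level_col, "prop_work")
  if (!all(req %in% names(data))) stop("missing required columns")
  data$beneficiary <- factor(data$beneficiary)
  data$.lev <- factor(data[[level_col]])
  k <- nlevels(data$.lev)
  # wide matrix with one column per (level, beneficiary) cell
  cells <- expand.grid(lev = levels(data$.lev),
                       ben = levels(data$beneficiary))
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sub <- data[data$beneficiary == cells$ben[i] & data$.lev == cells$lev[i], ]
    sub <- sub[order(sub$participant_id), ]
    sub$prop_work
  })
  ids <- sort(unique(data$participant_id))
  if (nrow(Y) != length(ids) || any(is.na(Y)))
    stop("missing cells: every participant needs every beneficiary x level cell")

  effects <- c("beneficiary", level_col, paste0("beneficiary:", level_col))
  if (stats::var(as.vector(Y)) < 1e-14 ||
      all(apply(Y, 1, stats::var) < 1e-14)) {
    return(data.frame(name = effects, statistic = 0,
                      df1 = c(1, k - 1, k - 1) ,
                      df2 = rep(length(ids) - 1, 3) * c(1, k - 1, k - 1),
                      p = 1, effect_size = 0, gg_epsilon = 1,
                      stringsAsFactors = FALSE))
  }

  idata <- data.frame(ben = factor(cells$ben), lev = factor(cells$lev))
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = ~ ben * lev, type = "III")
  # car warns when the Huynh-Feldt epsilon exceeds 1; only GG is used here
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- sm$univariate.tests
  adj <- sm$pval.adjustments

  rows <- c("ben", "lev", "ben:lev")
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    rn <- rows[i]
    ss <- ut[rn, "Sum Sq"]; sse <- ut[rn, "Error SS"]
    df1 <- ut[rn, "num Df"]; df2 <- ut[rn, "den Df"]
    Fv <- ut[rn, "F value"]; p <- ut[rn, "Pr(>F)"]
    eps <- 1
    if (!is.null(adj) && rn %in% rownames(adj)) {
      eps <- adj[rn, "GG eps"]
      p <- adj[rn, "Pr(>F[GG])"]
    }
    data.frame(name = effects[i], statistic = Fv, df1 = df1 * eps,
               df2 = df2 * eps, p = p,
               effect_size = ss / (ss + sse), gg_epsilon = eps,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-participant proportion of work choices by design cell
#'
#' Aggregates effort-task choice records into the per-cell proportions fed
#' to [rm_anova_2way()]; missed trials are excluded from the denominator.
#'
#' @param effort_trials Long effort-task records with `participant_id`,
#'   `beneficiary`, a cell column, `choice`, `missed`.
#' @param by Cell column: `"effort_level"` or `"reward"`.
#' @return Long data frame: `participant_id`, `beneficiary`, cell column,
#'   `prop_work`.
#' @export
work_proportions <- function(effort_trials, by = "effort_level") {
  ok <- !effort_trials$missed
  dat <- effort_trials[ok, , drop = FALSE]
  agg <- stats::aggregate(
    list(prop_work = dat$choice == "work"),
    by = list(participant_id = dat$participant_id,
              beneficiary = dat$beneficiary, cell = dat[[by]]),
    FUN = mean)
  names(agg)[names(agg) == "cell"] <- by
  agg
}
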
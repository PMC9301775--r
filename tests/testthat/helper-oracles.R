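# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the package implementation it checks.

# Exact null moments of the Wilcoxon signed-rank statistic W by enumerating
# all 2^n sign patterns over the given absolute-difference ranks (average
# ranks allowed, so ties are handled exactly).
enumerate_signed_rank <- function(ranks) {
  n <- length(ranks)
  stopifnot(n <= 14)
  W <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0
    sum(ranks[signs])
  }, numeric(1))
  list(mean = mean(W), var = mean((W - mean(W))^2), dist = W)
}

# Dense grid-search oracle for the harm model NLL (per-condition grids,
# exploiting that the likelihood separates over conditions).
harm_grid_nll <- function(records, kappa_step = 0.01,
                          beta_grid = c(0.5, 1, 2, 5, 10, 20)) {
  total <- 0
  for (cond in c("self", "other")) {
    rec <- records[records$beneficiary == cond & !records$is_attention_check, ]
    y <- rec$choice == "harmful"
    kg <- seq(0, 1, by = kappa_step)
    best <- Inf
    for (b in beta_grid) {
      for (k in kg) {
        dv <- (1 - k) * rec$d_money - k * rec$d_shocks
        p <- plogis(b * dv)
        pobs <- pmax(ifelse(y, p, 1 - p), 1e-12)
        nll <- -sum(log(pobs))
        if (nll < best) best <- nll
      }
    }
    total <- total + best
  }
  total
}

# Dense grid-search oracle for the effort model NLL.  For a fixed shared
# beta the two lambdas decouple, so the grid is beta x (lambda per
# condition).
effort_grid_nll <- function(records, lambda_step = 0.005,
                            beta_grid = c(0.5, 1, 2, 5, 10)) {
  records <- records[!records$missed, ]
  records$effort_units <- records$effort_level / 10
  lg <- seq(0, 0.5, by = lambda_step)
  best <- Inf
  for (b in beta_grid) {
    tot_b <- 0
    for (cond in c("self", "other")) {
      rec <- records[records$beneficiary == cond, ]
      y <- rec$choice == "work"
      cond_best <- Inf
      for (l in lg) {
        sv <- rec$reward - l * rec$effort_units^2
        p <- plogis(b * (sv - 1))
        pobs <- pmax(ifelse(y, p, 1 - p), 1e-12)
        nll <- -sum(log(pobs))
        if (nll < cond_best) cond_best <- nll
      }
      tot_b <- tot_b + cond_best
    }
    if (tot_b < best) best <- tot_b
  }
  best
}

# Brute-force first canonical correlation: direct numerical maximization of
# cor(Xa, Yb) over the weight vectors (scale-invariant, so unconstrained
# optimization works), multi-start BFGS.
bruteforce_cca_r1 <- function(X, Y, n_starts = 8, seed = 42) {
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  p <- ncol(X); q <- ncol(Y)
  obj <- function(par) {
    a <- par[seq_len(p)]; b <- par[p + seq_len(q)]
    xa <- X %*% a; yb <- Y %*% b
    if (sd(xa) < 1e-12 || sd(yb) < 1e-12) return(0)
    -abs(cor(xa, yb))
  }
  set.seed(seed)
  best <- 0
  for (i in seq_len(n_starts)) {
    res <- optim(rnorm(p + q), obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- max(best, -res$value)
  }
  best
}

# All-subsets commonality oracle: computes every commonality coefficient
# C(S) by Mobius inversion of f(S) = R2(all) - R2(all \ S), with R2 taken
# from lm() fits, then aggregates to unique/common/total per predictor.
allsubsets_commonality <- function(predictors, criterion) {
  Xp <- as.matrix(predictors)
  k <- ncol(Xp)
  subsets <- lapply(seq_len(2^k - 1), function(mask)
    which(bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0))
  r2 <- function(idx) {
    if (length(idx) == 0) return(0)
    summary(lm(criterion ~ Xp[, idx, drop = FALSE]))$r.squared
  }
  r2_full <- r2(seq_len(k))
  f <- vapply(subsets, function(S) r2_full - r2(setdiff(seq_len(k), S)),
              numeric(1))
  key <- vapply(subsets, function(S) sum(2L^(S - 1L)), numeric(1))
  f_of <- function(S) f[match(sum(2L^(S - 1L)), key)]
  C <- vapply(subsets, function(S) {
    sub <- subsets[vapply(subsets, function(T) all(T %in% S), logical(1))]
    sum(vapply(sub, function(T)
      (-1)^(length(S) - length(T)) * f_of(T), numeric(1)))
  }, numeric(1))
  out <- data.frame(variable = colnames(Xp), unique = NA_real_,
                    common = NA_real_, total = NA_real_)
  for (j in seq_len(k)) {
    has_j <- vapply(subsets, function(S) j %in% S, logical(1))
    only_j <- vapply(subsets, function(S) identical(S, j), logical(1))
    out$unique[j] <- C[only_j]
    out$total[j] <- sum(C[has_j])
    out$common[j] <- out$total[j] - out$unique[j]
  }
  out
}

# Shared small fixtures -------------------------------------------------

true_harm_params <- function(ks = 0.3, ko = 0.6, b = 5)
  list(kappa_self = ks, kappa_other = ko, beta_self = b, beta_other = b)

true_effort_params <- function(ls = 0.02, lo = 0.10, b = 2)
  list(lambda_self = ls, lambda_other = lo, beta = b)
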
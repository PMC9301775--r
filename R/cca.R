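#' Canonical correlation analysis with structure coefficients
#'
#' Finds pairs of linear combinations (canonical variates) of two variable
#' sets with maximal correlation, subject to unit variance and
#' orthogonality with earlier pairs.  Columns are z-scored (n - 1
#' denominator) before analysis, so the returned weights are standardized
#' function coefficients.  The solver whitens each set symmetrically
#' (inverse square root of its correlation matrix) and takes the singular
#' value decomposition of the whitened cross-correlation, which is
#' numerically stable and yields the canonical correlations directly as
#' singular values.
#'
#' Loadings (structure coefficients) are the correlations of each observed
#' variable with its own set's variate; cross-loadings are correlations
#' with the opposite set's variate and satisfy
#' `cross = loading * canonical r` exactly.  The sign of each function is
#' fixed so that the first Y variable's loading is positive.
#'
#' @param X Numeric matrix or data frame, n x p (the larger set, e.g. 18
#'   trait scores).
#' @param Y Numeric matrix or data frame, n x q (e.g. the 2 prosociality
#'   indices).
#' @return Object of class `cca_result`: `cor` (canonical correlations,
#'   decreasing), `x_weights`, `y_weights` (standardized, p x k and q x k),
#'   `x_loadings`, `y_loadings`, `x_cross`, `y_cross`, `x_scores`,
#'   `y_scores` (n x k, unit variance), `n`, `p`, `q`, and `significance`
#'   (sequential Wilks/Rao table from [cca_significance()]).
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (anyNA(X) || anyNA(Y)) stop("missing values: apply listwise deletion first")
  if (n <= p + q) stop("need n > p + q observations")
  for (set in list(list(M = X, nm = "X"), list(M = Y, nm = "Y"))) {
    qrd <- qr(scale(set$M, scale = FALSE))
    if (qrd$rank < ncol(set$M)) {
      bad <- colnames(set$M)[qrd$pivot[seq.int(qrd$rank + 1, ncol(set$M))]]
      stop(sprintf("rank-deficient %s: redundant column(s) %s",
                   set$nm, paste(bad, collapse = ", ")))
    }
  }
  Xs <- scale(X); Ys <- scale(Y)
  Rxx <- stats::cor(X); Ryy <- stats::cor(Y); Rxy <- stats::cor(X, Y)

  inv_sqrt <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values))
      stop("correlation matrix numerically singular")
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
      t(e$vectors)
  }
  Wx <- inv_sqrt(Rxx); Wy <- inv_sqrt(Ryy)
  K <- Wx %*% Rxy %*% Wy
  sv <- svd(K, nu = min(p, q), nv = min(p, q))
  k <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  A <- Wx %*% sv$u           # standardized X weights
  B <- Wy %*% sv$v           # standardized Y weights

  y_load <- Ryy %*% B
  flip <- ifelse(y_load[1, ] < 0, -1, 1)
  A <- sweep(A, 2, flip, `*`); B <- sweep(B, 2, flip, `*`)

  x_scores <- Xs %*% A; y_scores <- Ys %*% B
  x_load <- Rxx %*% A; y_load <- Ryy %*% B
  x_cross <- sweep(x_load, 2, r, `*`)
  y_cross <- sweep(y_load, 2, r, `*`)

  dn <- function(M, rn) {
    rownames(M) <- rn
    colnames(M) <- paste0("CV", seq_len(ncol(M)))
    M
  }
  xn <- colnames(X) %||% paste0("x", seq_len(p))
  yn <- colnames(Y) %||% paste0("y", seq_len(q))
  structure(list(
    cor = r,
    x_weights = dn(A, xn), y_weights = dn(B, yn),
    x_loadings = dn(x_load, xn), y_loadings = dn(y_load, yn),
    x_cross = dn(x_cross, xn), y_cross = dn(y_cross, yn),
    x_scores = dn(x_scores, NULL), y_scores = dn(y_scores, NULL),
    n = n, p = p, q = q,
    significance = cca_significance(r, n, p, q)
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("Canonical correlation analysis: n = %d, p = %d, q = %d\n",
              x$n, x$p, x$q))
  print(x$significance, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sequential Wilks/Rao significance tests for canonical correlations
#'
#' For each function k, tests whether canonical correlations k..m are
#' jointly zero: `Lambda_k = prod_(i>=k) (1 - r_i^2)`, converted to an F
#' statistic by Rao's approximation.  Following the sequential convention
#' of the standard statistical packages, the effective sample size when
#' testing function k is `n - k + 1` (one observation-equivalent is
#' consumed per partialled-out function), which reproduces the familiar
#' printed degrees of freedom (e.g. F(36, 610) then F(17, 306) for p = 18,
#' q = 2, n = 325).
#'
#' @param r Canonical correlations, sorted decreasing.
#' @param n,p,q Sample size and the two set sizes.
#' @return Data frame with one row per function: `k`, `r`, `wilks`, `F`,
#'   `df1`, `df2`, `p`.
#' @export
cca_significance <- function(r, n, p, q) {
  m <- length(r)
  out <- lapply(seq_len(m), function(k) {
    pp <- p - k + 1; qq <- q - k + 1
    lambda <- prod(1 - r[k:m]^2)
    df1 <- pp * qq
    s2 <- (pp^2 * qq^2 - 4) / (pp^2 + qq^2 - 5)
    s <- if (pp^2 + qq^2 - 5 > 0 && s2 > 0) sqrt(s2) else 1
    w <- (n - k + 1) - (pp + qq + 3) / 2
    df2 <- w * s - df1 / 2 + 1
    lam_s <- lambda^(1 / s)
    Fv <- if (lambda >= 1) 0 else (1 - lam_s) / lam_s * df2 / df1
    data.frame(k = k, r = r[k], wilks = lambda, F = Fv,
               df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Permutation test on Roy's largest root
#'
#' Nonparametric significance test for the first canonical correlation:
#' the rows of Y are permuted jointly (keeping each set's internal
#' structure intact), the largest squared canonical correlation is
#' recomputed for each permutation, and
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.  The computation reuses
#' the whitened data, so each permutation costs only one small
#' cross-product.
#'
#' @param X,Y Variable sets as in [fit_cca()].
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return List: `p` (permutation p-value), `statistic` (observed largest
#'   squared canonical correlation), `perm_stats` (null statistics).
#' @export
cca_permutation_test <- function(X, Y, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Xs <- scale(X); Ys <- scale(Y)
  inv_sqrt <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                       nrow = length(e$values)) %*% t(e$vectors)
  }
  Xw <- Xs %*% inv_sqrt(crossprod(Xs) / (n - 1))
  Yw <- Ys %*% inv_sqrt(crossprod(Ys) / (n - 1))
  largest_r2 <- function(perm) {
    C <- crossprod(Xw[perm, , drop = FALSE], Yw) / (n - 1)
    max(eigen(crossprod(C), symmetric = TRUE, only.values = TRUE)$values)
  }
  obs <- largest_r2(seq_len(n))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  perm_stats <- vapply(seq_len(n_perm),
                       function(i) largest_r2(sample.int(n)), numeric(1))
  list(p = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
       statistic = obs, perm_stats = perm_stats)
}

#' Commonality analysis of a set of predictors for one criterion
#'
#' Partitions each predictor's explanatory power for the criterion (here,
#' the opposite set's canonical variate) into a unique part and a part
#' shared with the other predictors: `total` is the squared zero-order
#' correlation with the criterion, `unique` is the drop in model R-squared
#' when the predictor is removed from the full regression, and
#' `common = total - unique`.  Negative common components are meaningful
#' and flag suppression.
#'
#' @param predictors Numeric matrix or data frame of predictors (at most
#'   20 columns; the all-subsets interpretation underlying the partition is
#'   combinatorial).
#' @param criterion Numeric criterion vector (e.g. canonical variate
#'   scores for function 1).
#' @return Data frame: `variable`, `unique`, `common`, `total` (R-squared
#'   units), with `unique + common == total` to machine precision.
#' @export
commonality_analysis <- function(predictors, criterion) {
  Xp <- as.matrix(predictors)
  k <- ncol(Xp)
  if (k > 20) stop("more than 20 predictors: all-subsets partition infeasible")
  if (length(criterion) != nrow(Xp))
    stop("criterion length must match predictor rows")
  R <- stats::cor(cbind(Xp, criterion))
  rxx <- R[seq_len(k), seq_len(k), drop = FALSE]
  rxy <- R[seq_len(k), k + 1]
  r2 <- function(idx) {
    if (length(idx) == 0L) return(0)
    drop(crossprod(rxy[idx], solve(rxx[idx, idx, drop = FALSE], rxy[idx])))
  }
  r2_full <- r2(seq_len(k))
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    total <- rxy[j]^2
    unique_j <- r2_full - r2(setdiff(seq_len(k), j))
    data.frame(variable = colnames(Xp)[j] %||% paste0("x", j),
               unique = unique_j, common = total - unique_j, total = total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify variables by loading/weight pattern on one canonical function
#'
#' Interprets one canonical function with the conventional 0.3 cutoff for
#' moderate-to-high coefficients: variables high on both loading and
#' weight are contributors; high loading with low weight flags
#' multicollinearity (the variable's variance is carried by others); low
#' loading with high weight flags a suppressor candidate; the rest are
#' negligible.
#'
#' @param loadings,weights Numeric vectors (one canonical function's
#'   coefficients, same length and order).
#' @param cross_loadings Optional cross-loadings, carried through to the
#'   output.
#' @param threshold Absolute-coefficient cutoff (default 0.3).
#' @return Data frame: `variable`, `loading`, `weight`, `cross_loading`,
#'   `role` in `contributor`, `collinear-contributor`,
#'   `suppressor-candidate`, `negligible`.
#' @export
classify_cca_roles <- function(loadings, weights, cross_loadings = NULL,
                               threshold = 0.3) {
  stopifnot(length(loadings) == length(weights))
  hl <- abs(loadings) >= threshold
  hw <- abs(weights) >= threshold
  role <- ifelse(hl & hw, "contributor",
          ifelse(hl & !hw, "collinear-contributor",
          ifelse(!hl & hw, "suppressor-candidate", "negligible")))
  data.frame(
    variable = names(loadings) %||% paste0("x", seq_along(loadings)),
    loading = as.numeric(loadings), weight = as.numeric(weights),
    cross_loading = if (is.null(cross_loadings)) NA_real_
                    else as.numeric(cross_loadings),
    role = role, stringsAsFactors = FALSE, row.names = NULL)
}
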
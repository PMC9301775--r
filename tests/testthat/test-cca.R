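test_that("CCA returns min(p, q) functions and handles identity relations", {
  set.seed(20)
  X <- matrix(rnorm(325 * 18), 325)
  colnames(X) <- trait_names()
  Y <- matrix(rnorm(325 * 2), 325)
  colnames(Y) <- c("hyperaltruism", "prosocial_effort")
  f <- fit_cca(X, Y)
  expect_length(f$cor, 2)
  expect_true(all(diff(f$cor) <= 0))
  expect_true(all(f$cor >= 0 & f$cor <= 1))
  # variate scores have unit variance; within-set variates uncorrelated
  expect_equal(apply(f$x_scores, 2, var), c(CV1 = 1, CV2 = 1),
               tolerance = 1e-10)
  expect_lt(abs(cor(f$x_scores)[1, 2]), 1e-10)
  expect_lt(abs(cor(f$y_scores)[1, 2]), 1e-10)
  # sign convention: first Y variable loads positively
  expect_true(all(f$y_loadings[1, ] >= 0))

  # Y a copy of two X columns -> both canonical correlations are 1
  Yc <- X[, c(3, 11)]
  colnames(Yc) <- c("a", "b")
  expect_equal(fit_cca(X, Yc)$cor, c(1, 1), tolerance = 1e-8)

  # rank-deficient input errors, naming the offending column
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(fit_cca(Xbad, Y), "rank-deficient X.*dup")
})

test_that("cross-loading identity and closed-form limits hold", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(60 * 4), 60); colnames(X) <- paste0("x", 1:4)
    Y <- matrix(rnorm(60 * 2), 60) + 0.4 * X[, 1:2]
    colnames(Y) <- paste0("y", 1:2)
    f <- fit_cca(X, Y)
    expect_lt(max(abs(f$x_cross - sweep(f$x_loadings, 2, f$cor, `*`))), 1e-10)
    expect_lt(max(abs(f$y_cross - sweep(f$y_loadings, 2, f$cor, `*`))), 1e-10)
  }
  # q = 1: canonical correlation equals the multiple correlation
  X <- matrix(rnorm(80 * 3), 80); colnames(X) <- paste0("x", 1:3)
  y <- X %*% c(1, -0.5, 0.2) + rnorm(80)
  f1 <- fit_cca(X, cbind(y = y))
  R2 <- summary(lm(y ~ X))$r.squared
  expect_equal(f1$cor[1], sqrt(R2), tolerance = 1e-10)
  # p = q = 1: canonical correlation is |Pearson r|, weights +-1
  x <- rnorm(50); y1 <- -x + rnorm(50)
  f2 <- fit_cca(cbind(x = x), cbind(y = y1))
  expect_equal(f2$cor[1], abs(cor(x, y1)), tolerance = 1e-12)
  expect_equal(abs(f2$x_weights[1, 1]), 1, tolerance = 1e-12)
  expect_equal(abs(f2$y_weights[1, 1]), 1, tolerance = 1e-12)
})

test_that("first canonical correlation matches brute-force maximization and cancor", {
  set.seed(22)
  X <- matrix(rnorm(50 * 3), 50); colnames(X) <- paste0("x", 1:3)
  Y <- matrix(rnorm(50 * 2), 50); Y[, 1] <- Y[, 1] + 0.8 * X[, 2]
  colnames(Y) <- paste0("y", 1:2)
  f <- fit_cca(X, Y)
  expect_equal(f$cor[1], bruteforce_cca_r1(X, Y), tolerance = 1e-4)
  expect_equal(f$cor, cancor(scale(X), scale(Y))$cor, tolerance = 1e-10)
})

test_that("sequential Wilks/Rao tests reproduce the standard dfs", {
  sig <- cca_significance(c(0.37, 0.30), n = 325, p = 18, q = 2)
  expect_equal(sig$df1, c(36, 17))
  expect_equal(sig$df2, c(610, 306))
  expect_equal(sig$wilks, c((1 - 0.37^2) * (1 - 0.3^2), 1 - 0.3^2),
               tolerance = 1e-12)
  expect_equal(round(sig$F[1], 2), 2.18)
  # all-zero correlations: Lambda = 1, F = 0
  sig0 <- cca_significance(c(0, 0), n = 100, p = 5, q = 2)
  expect_equal(sig0$wilks, c(1, 1))
  expect_equal(sig0$F, c(0, 0))
})

test_that("permutation test is seeded, exchangeable, and side-symmetric", {
  set.seed(23)
  pl <- planted_structure(r_target = 0.4)
  ct <- generate_trait_cohort(325, pl, seed = 24)
  X <- as.matrix(ct$traits[, trait_names()])
  Y <- cbind(ct$ground_truth$hyperaltruism, ct$ground_truth$prosocial_effort)
  p1 <- cca_permutation_test(X, Y, n_perm = 200, seed = 25)
  p2 <- cca_permutation_test(X, Y, n_perm = 200, seed = 25)
  expect_identical(p1$p, p2$p)
  expect_lt(p1$p, 0.05)
  # permuting X instead of Y gives the same distribution family; the
  # observed statistic is identical
  p3 <- cca_permutation_test(Y, X, n_perm = 200, seed = 26)
  expect_equal(p1$statistic, p3$statistic, tolerance = 1e-10)
  expect_lt(p3$p, 0.05)
  expect_error(cca_permutation_test(X, Y, n_perm = 50), "at least 100")
})

test_that("commonality partition matches the all-subsets oracle", {
  set.seed(27)
  # two orthogonal predictors: no common variance
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  crit <- a + 0.5 * b + rnorm(n)
  cm <- commonality_analysis(cbind(a = a, b = b), crit)
  oc <- allsubsets_commonality(cbind(a = a, b = b), crit)
  expect_equal(cm$unique, oc$unique, tolerance = 1e-10)
  expect_equal(cm$common, oc$common, tolerance = 1e-10)
  expect_lt(max(abs(cm$common)), 0.05)  # near zero for orthogonal draws

  # correlated 6-predictor fixture
  Z <- matrix(rnorm(n * 3), n)
  P <- cbind(Z, Z[, 1] + 0.5 * matrix(rnorm(n * 3), n))
  colnames(P) <- paste0("p", 1:6)
  crit2 <- Z %*% c(1, -1, 0.5) + rnorm(n)
  cm2 <- commonality_analysis(P, crit2)
  oc2 <- allsubsets_commonality(P, crit2)
  expect_equal(cm2$unique, oc2$unique, tolerance = 1e-10)
  expect_equal(cm2$common, oc2$common, tolerance = 1e-10)
  expect_equal(cm2$total, oc2$total, tolerance = 1e-10)
  # identity: unique + common = total
  expect_lt(max(abs(cm2$unique + cm2$common - cm2$total)), 1e-12)
  expect_error(commonality_analysis(matrix(rnorm(25 * 21), 25), rnorm(25)),
               "20 predictors")
})

test_that("a classical suppressor yields negative common and near-zero total", {
  set.seed(28)
  n <- 2000
  noise <- rnorm(n)                 # irrelevant variance
  signal <- rnorm(n)
  pred <- signal + noise            # valid predictor contaminated by noise
  supp <- noise + 0.3 * rnorm(n)    # suppressor: tracks only the noise
  crit <- signal + 0.5 * rnorm(n)
  cm <- commonality_analysis(cbind(pred = pred, supp = supp), crit)
  srow <- cm[cm$variable == "supp", ]
  expect_lt(srow$common, 0)
  expect_lt(abs(srow$total), 0.02)
  expect_gt(srow$unique, 0)
})

test_that("role classification follows the loading/weight thresholds", {
  roles <- classify_cca_roles(
    loadings = c(a = 0.8, b = 0.6, c = 0.1, d = 0.05),
    weights = c(0.7, 0.05, 0.5, 0.1))
  expect_equal(roles$role,
               c("contributor", "collinear-contributor",
                 "suppressor-candidate", "negligible"))
  # negative coefficients count by magnitude
  roles2 <- classify_cca_roles(c(x = -0.45), c(-0.31))
  expect_equal(roles2$role, "contributor")
})

test_that("planted traits are the ones recovered as contributors", {
  set.seed(29)
  pl <- planted_structure(r_target = 0.4)
  planted_vars <- names(which(abs(pl$loadings) >= 0.3))
  hit <- replicate(20, {
    ct <- generate_trait_cohort(325, pl, seed = sample.int(1e6, 1))
    f <- fit_cca(as.matrix(ct$traits[, trait_names()]),
                 cbind(hyperaltruism = ct$ground_truth$hyperaltruism,
                       prosocial_effort = ct$ground_truth$prosocial_effort))
    roles <- classify_cca_roles(f$x_loadings[, 1], f$x_weights[, 1])
    got <- roles$variable[roles$role %in%
                            c("contributor", "collinear-contributor")]
    all(planted_vars %in% got)
  })
  expect_gte(mean(hit), 0.9)
})
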
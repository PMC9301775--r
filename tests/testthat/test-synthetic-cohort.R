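test_that("harm trial set has the standard structure and identifiable ratios", {
  trials <- generate_harm_trialset(seed = 11)
  reg <- trials[!trials$is_attention_check, ]
  chk <- trials[trials$is_attention_check, ]
  expect_equal(nrow(reg), 70)
  expect_equal(nrow(chk), 4)
  expect_equal(unname(table(reg$beneficiary)), c(35L, 35L), ignore_attr = TRUE)
  # regular trials are genuine trade-offs
  expect_true(all(reg$d_money > 0 & reg$d_shocks > 0))
  # checks contain a dominated option
  expect_true(all(sign(chk$d_money) * sign(chk$d_shocks) < 0))
  # implied indifference ratios cover at least 8 of 10 deciles of (0, 1)
  ratio <- reg$d_money / (reg$d_money + reg$d_shocks)
  expect_gte(length(unique(pmin(floor(ratio * 10), 9))), 8)
  # deltas respect the configured ranges
  expect_true(all(reg$d_money >= 0.1 & reg$d_money <= 10))
  expect_true(all(reg$d_shocks >= 1 & reg$d_shocks <= 19))
})

test_that("harm trial generator honours counts, seeds and degenerate ranges", {
  small <- generate_harm_trialset(n_regular_per_condition = 1,
                                  n_checks_per_condition = 0, seed = 2)
  expect_equal(nrow(small), 2)
  expect_true(all(small$d_money > 0 & small$d_shocks > 0))
  expect_identical(generate_harm_trialset(seed = 7),
                   generate_harm_trialset(seed = 7))
  expect_error(generate_harm_trialset(money_range = c(2, 2)), "degenerate")
})

test_that("effort trial set is the balanced 48-trial design", {
  eff <- generate_effort_trialset()
  expect_equal(nrow(eff), 48)
  expect_equal(unname(table(eff$beneficiary)), c(24L, 24L),
               ignore_attr = TRUE)
  cells <- table(eff$beneficiary, eff$effort_level, eff$reward)
  expect_true(all(cells == 2))
  units <- unique(eff[order(eff$effort_level), c("effort_level",
                                                 "effort_units")])
  expect_true(all(diff(units$effort_units) > 0))
  expect_true(all(eff$rest_reward == 1))
})

test_that("simulated harm choices follow the softmax model", {
  trials <- generate_harm_trialset(seed = 3)
  # kappa = 1, steep beta: helpful virtually always chosen on regular trials
  det <- simulate_harm_choices(
    list(kappa_self = 1, kappa_other = 1, beta_self = 100, beta_other = 100),
    trials, seed = 4)
  reg <- det[!det$is_attention_check, ]
  expect_true(all(reg$choice == "helpful"))
  # kappa = 0: dV = d_money > 0 so P(harmful) > 0.5 on every regular trial
  p0 <- p_harmful(harm_delta_value(reg$d_money, reg$d_shocks, 0), 5)
  expect_true(all(p0 > 0.5))
  # beta = 0: empirical choice rate ~ 0.5
  one <- trials[rep(1, 10000), ]
  flip <- simulate_harm_choices(
    list(kappa_self = 0.5, kappa_other = 0.5, beta_self = 0, beta_other = 0),
    one, seed = 5)
  expect_lt(abs(mean(flip$choice == "harmful") - 0.5), 0.02)
})

test_that("simulated choice frequencies converge to model probabilities", {
  trials <- generate_harm_trialset(seed = 6)[c(3, 12, 20), ]
  pars <- true_harm_params(0.4, 0.4, 2)
  p_true <- p_harmful(harm_delta_value(trials$d_money, trials$d_shocks, 0.4), 2)
  big <- trials[rep(1:3, each = 10000), ]
  sim <- simulate_harm_choices(pars, big, seed = 7)
  emp <- tapply(sim$choice == "harmful", rep(1:3, each = 10000), mean)
  expect_lt(max(abs(emp - p_true)), 0.02)
})

test_that("simulated effort choices respect bounds and miss rate", {
  eff <- generate_effort_trialset()
  # lambda = 0: every offer beats rest (R >= 2 > 1) so P(work) > 0.5
  sv0 <- effort_subjective_value(eff$reward, eff$effort_units, 0)
  expect_true(all(p_work(sv0, 0.7) > 0.5))
  # lambda at the 0.5 cap: all offers fall below rest
  sv_cap <- effort_subjective_value(eff$reward, eff$effort_units, 0.5)
  expect_true(all(sv_cap < 1))
  expect_true(all(p_work(sv_cap, 2) < 0.5))
  # binomial mean of missed count at miss_rate 0.2
  set.seed(99)
  miss <- replicate(1000, {
    sum(simulate_effort_choices(true_effort_params(), eff,
                                seed = sample.int(1e6, 1),
                                miss_rate = 0.2)$missed)
  })
  expect_lt(abs(mean(miss) - 9.6), 0.5)
  # missed trials carry no recorded choice
  simm <- simulate_effort_choices(true_effort_params(), eff, seed = 1,
                                  miss_rate = 0.3)
  expect_true(all(is.na(simm$choice[simm$missed])))
  expect_true(all(!is.na(simm$choice[!simm$missed])))
})

test_that("trait cohort has 18 traits and hits the planted canonical correlation", {
  ct <- generate_trait_cohort(325, planted_structure(r_target = 0.4),
                              seed = 21)
  expect_equal(ncol(ct$traits) - 1L, 18L)
  expect_identical(names(ct$traits)[-1], trait_names())
  expect_false(anyNA(ct$traits))
  expect_true(all(ct$ground_truth$kappa_self >= 0 &
                    ct$ground_truth$kappa_other <= 1))
  expect_true(all(ct$ground_truth$lambda_other <= 0.5 &
                    ct$ground_truth$lambda_self >= 0))

  set.seed(123)
  r1 <- replicate(50, {
    c2 <- generate_trait_cohort(325, planted_structure(r_target = 0.4),
                                seed = sample.int(1e6, 1))
    fit_cca(as.matrix(c2$traits[, trait_names()]),
            cbind(c2$ground_truth$hyperaltruism,
                  c2$ground_truth$prosocial_effort))$cor[1]
  })
  expect_lt(abs(mean(r1) - 0.4), 0.1)
})

test_that("null cohort decouples traits from indices and infeasible targets error", {
  null_pl <- planted_structure(loadings = rep(0, 18), r_target = 0)
  ct <- generate_trait_cohort(400, null_pl, seed = 31)
  cors <- cor(as.matrix(ct$traits[, trait_names()]),
              ct$ground_truth$hyperaltruism)
  expect_lt(max(abs(cors)), 0.2)  # pure sampling noise at n = 400
  expect_error(planted_structure(r_target = 0.96), "infeasible")
  expect_error(planted_structure(loadings = rep(0, 18), r_target = 0.3),
               "infeasible")
})

test_that("cohorts round-trip through the CSV writers and readers", {
  cfg <- default_config(n = 8L, seed = 17L)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$trials, cohort$trials, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$traits, cohort$traits, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$ground_truth, cohort$ground_truth, tolerance = 1e-12,
               ignore_attr = TRUE)
  # determinism: same config, same files
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$trials, cohort2$trials)
  expect_identical(cohort$traits, cohort2$traits)
})
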
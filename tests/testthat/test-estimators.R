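test_that("wald_ratio computes theta, first-order SE, and exact weights", {
  insts <- make_insts(beta_exp = c(1, 0.5, 2), beta_out = c(0.2, 0.1, 0),
                      se_out = c(0.1, 0.05, 0.1))
  wr <- wald_ratio(insts)
  expect_equal(wr$theta, c(0.2, 0.2, 0))
  expect_equal(wr$se, c(0.1, 0.1, 0.05))
  expect_equal(wr$weight, wr$se^-2)
  expect_error(wald_ratio(make_insts(beta_exp = c(1, 0),
                                     beta_out = c(0.1, 0.1))),
               class = "mrscreen_degenerate_instrument")
})

test_that("mr_ivw reproduces the hand-computed two-instrument fixture", {
  insts <- make_insts(beta_exp = c(1, 1), beta_out = c(0.2, 0.6),
                      se_out = c(0.1, 0.2))
  fit <- mr_ivw(insts)
  expect_equal(fit$estimate$beta, 0.28)
  expect_equal(fit$se_fixed, 0.08944272, tolerance = 1e-7)
  expect_equal(fit$q_stat, 3.2)
  expect_equal(fit$phi, 1.7888544, tolerance = 1e-7)
  expect_equal(fit$estimate$se, 0.16)
  expect_equal(fit$estimate$pvalue, 0.080, tolerance = 2e-2)
  expect_equal(fit$q_p, 0.0736, tolerance = 1e-3)

  # degenerate homogeneity: identical ratios
  same <- make_insts(beta_exp = c(1, 2), beta_out = c(0.5, 1.0))
  f2 <- mr_ivw(same)
  expect_equal(f2$estimate$beta, 0.5)
  expect_equal(f2$q_stat, 0)
  expect_equal(f2$phi, 1)
  expect_equal(f2$q_p, 1)

  expect_error(mr_ivw(same[1, ]),
               class = "mrscreen_insufficient_instruments")
})

test_that("mr_ivw equals weighted regression through the origin (oracle)", {
  set.seed(101)
  for (rep in 1:50) {
    insts <- random_insts(sample(3:30, 1))
    fit <- mr_ivw(insts)
    expect_equal(fit$estimate$beta, oracle_ivw_beta(insts),
                 tolerance = 1e-10)
  }
})

test_that("IVW satisfies its structural invariants", {
  set.seed(5)
  insts <- random_insts(12)
  fit <- mr_ivw(insts)
  # permutation invariance
  perm <- insts[sample(nrow(insts)), ]
  expect_equal(mr_ivw(perm)$estimate$beta, fit$estimate$beta)
  expect_equal(mr_ivw(perm)$q_stat, fit$q_stat)
  # scale equivariance in beta_exp
  sc <- insts; c0 <- 2.5
  sc$beta_exp <- sc$beta_exp * c0
  expect_equal(mr_ivw(sc)$estimate$beta, fit$estimate$beta / c0)
  # joint negation leaves the estimate unchanged
  neg <- insts
  neg$beta_exp <- -neg$beta_exp; neg$beta_out <- -neg$beta_out
  expect_equal(mr_ivw(neg)$estimate$beta, fit$estimate$beta)
  # two identical-precision instruments: simple mean of ratios
  two <- make_insts(beta_exp = c(1, 1), beta_out = c(0.1, 0.5),
                    se_out = 0.1)
  expect_equal(mr_ivw(two)$estimate$beta, 0.3)
  # Q nonnegative, zero iff ratios equal
  expect_gte(fit$q_stat, 0)
})

test_that("weighted_median_value interpolates the weighted quantile rule", {
  expect_equal(weighted_median_value(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median_value(c(1, 2, 3, 4), rep(1, 4)), 2.5)
  expect_equal(weighted_median_value(c(1, 2, 3), c(3, 1, 1)), 1.5)
  # dominant first weight: p = (5/12, 10.5/12, 11.5/12), interpolate
  expect_equal(weighted_median_value(c(1, 2, 3), c(10, 1, 1)), 13 / 11)
  # the boundary case only arises with a single value (p1 = w1/(2S) >= 0.5
  # requires w1 >= S)
  expect_equal(weighted_median_value(5, 2), 5)
  expect_error(weighted_median_value(numeric(0), numeric(0)),
               class = "mrscreen_domain_error")
  expect_error(weighted_median_value(c(1, 2), c(1, 0)),
               class = "mrscreen_domain_error")
  # equal weights, odd length: the sample median; order irrelevant
  set.seed(3)
  for (rep in 1:20) {
    v <- rnorm(2 * sample(2:10, 1) + 1)
    expect_equal(weighted_median_value(v, rep(1, length(v))), median(v))
    w <- runif(length(v), 0.1, 5)
    expect_equal(weighted_median_value(v, w),
                 oracle_weighted_median(v, w))
    p <- sample(length(v))
    expect_equal(weighted_median_value(v[p], w[p]),
                 weighted_median_value(v, w))
  }
})

test_that("mr_weighted_median is seeded, consistent, and bootstrap-stable", {
  insts <- make_insts(beta_exp = c(1, 2, 4), beta_out = c(0.5, 1.0, 2.0))
  est <- mr_weighted_median(insts, n_boot = 200, seed = 9)
  expect_equal(est$beta, 0.5)  # all ratios equal
  # determinism under a fixed seed
  est2 <- mr_weighted_median(insts, n_boot = 200, seed = 9)
  expect_equal(est$se, est2$se)
  expect_error(mr_weighted_median(insts[1:2, ]),
               class = "mrscreen_insufficient_instruments")

  # Monte-Carlo oracle: independent re-implementation of the same
  # parametric bootstrap agrees within 10% relative on the SE
  set.seed(21)
  insts <- random_insts(10)
  wr <- wald_ratio(insts)
  est <- mr_weighted_median(insts, n_boot = 2000, seed = 33)
  reps <- replicate(2000, oracle_weighted_median(
    rnorm(nrow(wr), wr$theta, wr$se), wr$weight))
  expect_lt(abs(est$se - sd(reps)) / sd(reps), 0.10)
})

test_that("mr_egger reproduces the 3-point fixture and the WLS oracle", {
  insts <- make_insts(beta_exp = c(1, 2, 3), beta_out = c(0.6, 1.1, 1.6),
                      se_out = 0.1)
  eg <- mr_egger(insts)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept, 0.1, tolerance = 1e-12)
  expect_equal(eg$phi, 1)  # perfect fit floors the dispersion at 1
  expect_equal(eg$slope$se, 0.0707107, tolerance = 1e-5)
  expect_equal(eg$intercept_se, 0.1527525, tolerance = 1e-5)

  # all-zero outcome: slope and intercept zero
  z <- make_insts(beta_exp = c(1, 2, 3), beta_out = c(0, 0, 0))
  expect_equal(mr_egger(z)$slope$beta, 0)
  expect_equal(mr_egger(z)$intercept, 0)

  # errors: too few instruments, collinearity
  expect_error(mr_egger(insts[1:2, ]),
               class = "mrscreen_insufficient_instruments")
  coll <- make_insts(beta_exp = c(1, 1, 1), beta_out = c(0.1, 0.2, 0.3))
  expect_error(mr_egger(coll), class = "mrscreen_collinearity_error")

  # oracle equality on random instances
  set.seed(202)
  for (rep in 1:50) {
    insts <- random_insts(sample(3:30, 1))
    eg <- mr_egger(insts)
    or <- oracle_egger(insts)
    expect_equal(eg$slope$beta, or$slope, tolerance = 1e-10)
    expect_equal(eg$intercept, or$intercept, tolerance = 1e-10)
  }
})

test_that("Egger equals IVW on noiseless proportional data and is invariant", {
  # exact proportionality, no pleiotropy: slope = theta, intercept = 0
  insts <- make_insts(beta_exp = c(0.1, 0.15, 0.2, 0.3),
                      beta_out = 0.4 * c(0.1, 0.15, 0.2, 0.3))
  eg <- mr_egger(insts)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-12)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(mr_ivw(insts)$estimate$beta, 0.4, tolerance = 1e-12)

  set.seed(77)
  insts <- random_insts(9)
  eg <- mr_egger(insts)
  perm <- insts[sample(nrow(insts)), ]
  expect_equal(mr_egger(perm)$slope$beta, eg$slope$beta)
  expect_equal(mr_egger(perm)$intercept, eg$intercept)
  # joint negation leaves Egger unchanged (orientation step)
  neg <- insts
  neg$beta_exp <- -neg$beta_exp; neg$beta_out <- -neg$beta_out
  expect_equal(mr_egger(neg)$slope$beta, eg$slope$beta)
  expect_equal(mr_egger(neg)$intercept, eg$intercept)
})

test_that("to_odds_ratio exponentiates the interval and matches reporting", {
  z <- to_odds_ratio(0, 0.1)
  expect_equal(z[["or_value"]], 1)
  expect_equal(z[["or_low"]] * z[["or_high"]], 1, tolerance = 1e-12)
  # OR-per-SD shape of published reporting, se back-solved from a 95% CI
  z <- to_odds_ratio(log(1.14), 0.0448, 1.96)
  expect_equal(z[["or_value"]], 1.14, tolerance = 1e-6)
  expect_equal(unname(z[c("or_low", "or_high")]), c(1.045, 1.245),
               tolerance = 5e-3)
  z <- to_odds_ratio(log(0.82), 0.0911, 1.96)
  expect_equal(unname(round(z[c("or_low", "or_high")], 2)), c(0.69, 0.98))
  expect_error(to_odds_ratio(0.1, 0), class = "mrscreen_domain_error")
})

test_that("mr_estimate keeps beta/OR scales consistent", {
  e <- mr_estimate("IVW", 0.2, 0.05, 0.01, 10)
  expect_lt(e$ci_low, e$beta); expect_gt(e$ci_high, e$beta)
  expect_equal(e$or_value, exp(e$beta))
  expect_equal(e$or_low, exp(e$ci_low))
  expect_equal(e$or_high, exp(e$ci_high))
})
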
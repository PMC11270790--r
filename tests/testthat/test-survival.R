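test_that("Kaplan-Meier reproduces hand product-limit computations", {
  # all censored: the curve never steps
  km0 <- km_estimate(c(2, 4, 6, 8, 10), rep(0, 5))
  expect_equal(survival_at(km0, c(0, 5, 100)), c(1, 1, 1))

  # four events: S(2) = (3/4)(2/3) = 1/2
  km1 <- km_estimate(1:4, rep(1, 4))
  expect_equal(survival_at(km1, 2), 0.5)

  # six-record table with censoring, hand product-limit
  km2 <- km_estimate(c(1, 1, 2, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(survival_at(km2, 1), 5 / 6, tolerance = 1e-10)
  expect_equal(survival_at(km2, 3), 5 / 6 * 3 / 4, tolerance = 1e-10)
  expect_equal(survival_at(km2, 4.5), 5 / 6 * 3 / 4 * 2 / 3,
               tolerance = 1e-10)
  expect_equal(survival_at(km2, 6), 0, tolerance = 1e-10)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("Kaplan-Meier converges to the exponential closed form", {
  set.seed(31)
  lam <- 0.03
  tt <- stats::rexp(2000, lam)
  km <- km_estimate(tt, rep(1, 2000))
  grid <- seq(0, stats::quantile(tt, 0.99), length.out = 200)
  expect_lt(max(abs(survival_at(km, grid) - exp(-lam * grid))), 0.05)
})

test_that("Kaplan-Meier is invariant to record order", {
  set.seed(4)
  tt <- round(stats::rexp(40, 0.1), 1)
  ev <- stats::rbinom(40, 1, 0.7)
  km <- km_estimate(tt, ev)
  p <- sample(40)
  kmp <- km_estimate(tt[p], ev[p])
  expect_identical(km$time, kmp$time)
  expect_identical(km$surv, kmp$surv)
})

test_that("the log-rank test matches a hand-computed O/E/V table", {
  # identical groups: no signal at all
  tA <- c(1, 3, 5, 7); eA <- c(1, 1, 0, 1)
  lr0 <- logrank(tA, eA, tA, eA)
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)

  # 8-record two-group table, expectation and variance accumulated per
  # event time by hand
  tB <- c(2, 4, 6, 8); eB <- c(1, 1, 1, 0)
  E <- 1 / 2 + 3 / 7 + 1 / 2 + 2 / 5 + 1 / 3 + 1 / 2
  V <- 1 / 4 + 12 / 49 + 1 / 4 + 6 / 25 + 2 / 9 + 1 / 4
  lr <- logrank(tA, eA, tB, eB)
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, E, tolerance = 1e-10)
  expect_equal(lr$chisq, (3 - E)^2 / V, tolerance = 1e-10)

  skip_if_not_installed("survival")
  sd <- survival::survdiff(
    survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, each = 4))
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank is symmetric in group labels and guards zero events", {
  set.seed(6)
  t1 <- stats::rexp(30, 0.1); e1 <- stats::rbinom(30, 1, 0.6)
  t2 <- stats::rexp(25, 0.15); e2 <- stats::rbinom(25, 1, 0.6)
  expect_equal(logrank(t1, e1, t2, e2)$chisq,
               logrank(t2, e2, t1, e1)$chisq, tolerance = 1e-12)
  expect_error(logrank(t1, rep(0, 30), t2, rep(0, 25)), "zero events")
})

test_that("a strong simulated effect is detected reliably", {
  hits <- 0
  for (i in 1:100) {
    coh <- simulate_cohort(cohort_spec(
      400, seed = 5000 + i, beta_pfs = c(g = log(3)), beta_os = numeric(0),
      scale_pfs = 70, censor_months = 60,
      extra_covariates = list(g = list(dist = "binary", p = 0.5))))
    g <- coh$g == 1
    p <- logrank(coh$pfs_months[!g], coh$pfs_event[!g],
                 coh$pfs_months[g], coh$pfs_event[g])$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("Cox estimates match a brute-force likelihood maximisation", {
  # small dataset, no ties: golden-section over the scalar partial
  # likelihood must land on the Newton solution
  set.seed(12)
  x <- rep(c(0, 1), each = 6)
  tt <- c(4.1, 2.3, 8.7, 5.5, 9.9, 12.4, 1.2, 3.3, 2.8, 6.6, 0.9, 7.7)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  fit <- cox_fit(matrix(x, ncol = 1), tt, ev)
  brute <- stats::optimize(function(b) oracle_cox_loglik(b, x, tt, ev),
                           c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), brute$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, brute$objective, tolerance = 1e-10)
})

test_that("Cox agrees with the survival package under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(19)
  n <- 150
  x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.4)
  tt <- round(stats::rexp(n, 0.1 * exp(0.5 * x1 + 0.7 * x2)), 0) + 0.5
  ev <- stats::rbinom(n, 1, 0.75)           # rounded times create ties
  X <- cbind(x1 = x1, x2 = x2)
  for (ties in c("breslow", "efron")) {
    ours <- cox_fit(X, tt, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2, ties = ties)
    expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("Cox satisfies its stationarity and null-recovery properties", {
  set.seed(23)
  n <- 1000
  x <- stats::rbinom(n, 1, 0.5)
  tt <- stats::rexp(n, 0.05)                # no true effect
  ev <- stats::rbinom(n, 1, 0.8)
  fit <- cox_fit(matrix(x, ncol = 1), tt, ev)
  expect_lt(abs(fit$coef), 0.15)
  expect_true(fit$ci_lower < 1 && fit$ci_upper > 1)
  expect_gte(fit$loglik, fit$loglik_null)

  # the score vanishes at the estimate
  sc <- mtapet:::.cox_loglik(fit$coef, matrix(x[order(tt)], ncol = 1),
                             sort(tt), ev[order(tt)], "breslow")$score
  expect_lt(max(abs(sc)), 1e-6)
})

test_that("Cox rejects degenerate designs and flags separation", {
  tt <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  expect_error(cox_fit(matrix(1, 6, 1), tt, ev), "constant")
  x <- c(0, 1, 0, 1, 0, 1)
  expect_error(cox_fit(cbind(x, x), tt, ev), "linearly dependent")

  # perfectly separated covariate: monotone likelihood is flagged
  xs <- c(1, 1, 1, 0, 0, 0)                 # all early events in one arm
  fit <- cox_fit(matrix(xs, ncol = 1), tt, ev)
  expect_false(fit$converged)
  expect_match(fit$message, "monotone")
})
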
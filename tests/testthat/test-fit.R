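test_that("log-likelihood evaluates the exact-death PH likelihood", {
  m <- gompertz_makeham(0.01, 0.005, 0.1)
  d1 <- tibble::tibble(age = 25, sex = 0)
  # ln h(10) - H(10), oracle-computed
  expect_equal(log_likelihood(d1, m), -3.932787, tolerance = 1e-6)
  expect_equal(log_likelihood(d1, m, rho = 5), log_likelihood(d1, m))
  # i.i.d. terms sum
  d2 <- dplyr::bind_rows(d1, d1)
  expect_equal(log_likelihood(d2, m), 2 * log_likelihood(d1, m))
  # x = 1 with rho = 0 equals the x = 0 value
  expect_equal(log_likelihood(tibble::tibble(age = 25, sex = 1), m, rho = 0),
               log_likelihood(d1, m))
  expect_error(log_likelihood(tibble::tibble(age = numeric(), sex = numeric()), m),
               "nonempty")
})

test_that("log-likelihood matches the brute-force sum of ln densities", {
  set.seed(11)
  # ages capped so the raw density oracle stays above the double underflow
  d <- dplyr::filter(sim_individuals(80, rho = 0.5, seed = 11), age <= 75)
  for (i in 1:20) {
    m <- random_gm(beta_max = 0.1)
    rho <- runif(1, -1, 1)
    brute <- sum(log(death_density(m, d$age - 15, x = d$sex, rho = rho)))
    expect_equal(log_likelihood(d, m, rho = rho), brute, tolerance = 1e-10)
  }
})

test_that("fitting recovers simulated parameters at large n", {
  d <- sim_individuals(5000, gompertz_makeham(0.005, 0.02, 0.09), rho = 0.3,
                       seed = 99)
  f <- fit_mortality(d, n_starts = 3)
  expect_true(f$converged)
  expect_true(all(is.finite(f$se)))
  # within 3 standard errors of the generating values
  truth <- c(a1 = 0.005, a2 = 0.02, beta = 0.09, rho = 0.3)
  expect_true(all(abs(f$coef - truth) < 3 * f$se))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(f)
  expect_equal(g$df, 4)
  expect_equal(g$AIC, -2 * f$loglik + 8)
})

test_that("fit validation catches unusable input", {
  d <- sim_individuals(100, seed = 2)
  expect_error(fit_mortality(dplyr::mutate(d, sex = 0)), "single level")
  expect_error(fit_mortality(d[1:5, ]), "at least")
  expect_error(fit_mortality(dplyr::mutate(d, age = age - 20)), ">= 15")
})

test_that("fitting is invariant to row order and deterministic by seed", {
  d <- sim_individuals(400, rho = 0.4, seed = 5)
  f1 <- fit_mortality(d, n_starts = 4, seed = 123)
  f2 <- fit_mortality(d[sample(nrow(d)), ], n_starts = 4, seed = 123)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
  f3 <- fit_mortality(d, n_starts = 4, seed = 123)
  expect_identical(f1$coef, f3$coef)   # bit-identical rerun
  expect_identical(f1$loglik, f3$loglik)
})

test_that("swapping the covariate labels flips the sign of rho", {
  d <- sim_individuals(800, rho = 0.5, seed = 8)
  f <- fit_mortality(d, n_starts = 3)
  f_flip <- fit_mortality(dplyr::mutate(d, sex = 1 - sex), n_starts = 3)
  expect_equal(f_flip$coef[["rho"]], -f$coef[["rho"]], tolerance = 1e-3)
  expect_equal(f_flip$loglik, f$loglik, tolerance = 1e-6)
})

test_that("Wald intervals use the normal quantile on the right scale", {
  f <- stub_fit(-100, covariate = TRUE)
  f$se["rho"] <- 1
  f$se_trans <- f$se
  f$theta <- c(0.1, 0.1, 0.1, 0)
  f$coef["rho"] <- 0
  f$level <- 0.95
  int <- wald_ci(f, "rho", 0.95)
  expect_equal(int$conf.low, -1.959964, tolerance = 1e-6)
  expect_equal(int$conf.high, 1.959964, tolerance = 1e-6)
  degen <- wald_ci(f, "rho", 0)
  expect_equal(degen$conf.low, degen$conf.high)
  # positive parameters get back-transformed bounds, hence stay positive
  d <- sim_individuals(500, seed = 3)
  fr <- fit_mortality(d, covariate = FALSE, n_starts = 3)
  for (p in c("a1", "a2", "beta")) {
    ci <- wald_ci(fr, p)
    expect_gt(ci$conf.low, 0)
    expect_true(ci$conf.low <= fr$coef[[p]] && fr$coef[[p]] <= ci$conf.high)
  }
})

test_that("profile and Wald intervals agree asymptotically", {
  d <- sim_individuals(3000, rho = 0.3, seed = 21)
  f <- fit_mortality(d, n_starts = 3)
  w <- wald_ci(f, "rho")
  p <- profile_ci(f, "rho")
  width <- w$conf.high - w$conf.low
  expect_lt(abs(p$conf.low - w$conf.low), 0.1 * width)
  expect_lt(abs(p$conf.high - w$conf.high), 0.1 * width)
  expect_true(p$conf.low < f$coef[["rho"]] && f$coef[["rho"]] < p$conf.high)
})

test_that("the LRT arithmetic and chi-square tail are exact", {
  full <- stub_fit(-100, covariate = TRUE)
  red <- stub_fit(-101, covariate = FALSE)
  r <- lrt(full, red)
  expect_equal(r$statistic, 2)
  expect_equal(r$df, 1)
  expect_equal(r$p.value, 0.157299, tolerance = 1e-5)
  # identical fits give stat 0, p 1
  same <- lrt(stub_fit(-100, TRUE), stub_fit(-100, FALSE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # clamped when the nested optimum marginally exceeds the full one
  clamp <- lrt(stub_fit(-100.001, TRUE), stub_fit(-100, FALSE))
  expect_equal(clamp$statistic, 0)
  expect_error(lrt(stub_fit(-100, TRUE),
                   stub_fit(-101, FALSE, digest = list(t = "other", tx = "o"))),
               "different data")
  expect_error(lrt(stub_fit(-100, FALSE), stub_fit(-101, TRUE)), "nested")
})

test_that("chi-square upper tail matches the normal-tail identity at df = 1", {
  expect_equal(chisq_upper_tail(0.51, 1), 0.475139, tolerance = 1e-5)
  expect_equal(chisq_upper_tail(0.51, 1), 2 * pnorm(sqrt(0.51), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(chisq_upper_tail(0, 5), 1)
  expect_equal(chisq_upper_tail(3.841459, 1), 0.05, tolerance = 1e-6)
  expect_error(chisq_upper_tail(-1, 1), "stat")
})

test_that("strata comparison reports per-stratum intervals and overlap", {
  m <- gompertz_makeham(0.01, 0.005, 0.07)
  set.seed(31)
  mk <- function(n, rho, period) {
    d <- sim_individuals(n, m, rho = rho, seed = sample.int(1e6, 1))
    dplyr::mutate(d, period = period)
  }
  # identical null strata: both intervals span zero and overlap
  d0 <- dplyr::bind_rows(mk(400, 0, "early"), mk(400, 0, "late"))
  c0 <- compare_strata(d0, n_starts = 2)
  expect_true(all(c0$summary$spans_zero))
  expect_true(c0$overlap)
  # strongly different effects at large n: non-overlapping intervals
  d1 <- dplyr::bind_rows(mk(2000, 0, "early"), mk(2000, 1.5, "late"))
  c1 <- compare_strata(d1, n_starts = 2)
  expect_false(c1$overlap)
  # single stratum: degenerate report, no comparison
  c2 <- compare_strata(mk(300, 0, "early"), n_starts = 2)
  expect_true(is.na(c2$overlap))
  # undersized stratum flagged, not fitted
  d3 <- dplyr::bind_rows(mk(300, 0, "early"), mk(5, 0, "late"))
  c3 <- compare_strata(d3, n_starts = 2)
  expect_false(c3$summary$fitted[c3$summary$stratum == "late"])
})
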
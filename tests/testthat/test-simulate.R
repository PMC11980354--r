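test_that("the age sampler matches the closed-form Gompertz inverse", {
  g <- gompertz(0.01, 0.08)
  set.seed(123)
  drawn <- sample_age(500, g, age_cap = 200)
  set.seed(123)
  u <- runif(500)
  closed <- 15 + log1p(0.08 * (-log(u)) / 0.01) / 0.08
  expect_equal(as.numeric(drawn), closed, tolerance = 1e-8)
})

test_that("sampled ages respect the entry age and the cap", {
  m <- gompertz_makeham(0.02, 0.01, 0.1)
  set.seed(9)
  a <- sample_age(2000, m, age_cap = 80)
  expect_true(all(a >= 15))
  expect_true(all(a <= 80))
  expect_true(is.numeric(attr(a, "resampled")))
})

test_that("the PH effect shows in the empirical survival curves", {
  m <- gompertz_makeham(0.005, 0.01, 0.08)
  set.seed(50)
  n <- 20000
  a0 <- as.numeric(sample_age(n, m, x = 0, rho = log(4), age_cap = 200))
  a1 <- as.numeric(sample_age(n, m, x = 1, rho = log(4), age_cap = 200))
  grid <- c(25, 35, 45, 55)
  s0 <- vapply(grid, function(g) mean(a0 > g), numeric(1))
  s1 <- vapply(grid, function(g) mean(a1 > g), numeric(1))
  expect_equal(s1, s0^4, tolerance = 0.05)
})

test_that("simulated death ages satisfy the unit-exponential transform", {
  m <- gompertz_makeham(0.01, 0.005, 0.07)
  rho <- 0.4
  set.seed(60)
  x <- rbinom(1e4, 1, 0.5)
  a <- as.numeric(sample_age(1e4, m, x = x, rho = rho, age_cap = 300))
  e <- exp(x * rho) * cumulative_hazard(m, a - 15)
  expect_equal(mean(e), 1, tolerance = 0.05)
})

test_that("assemblages are reproducible and component streams independent", {
  cfg <- sim_config(n = 120, seed = 42)
  a1 <- simulate_assemblage(cfg)
  a2 <- simulate_assemblage(cfg)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  # toggling downstream estimation does not shift the generative columns
  cfg_off <- sim_config(n = 120, seed = 42, estimate_age = FALSE,
                        estimate_sex = FALSE)
  a3 <- simulate_assemblage(cfg_off)
  gen_cols <- c("id", "site", "period", "sex", "age",
                names(default_trait_models()), measurement_columns())
  expect_equal(tibble::as_tibble(a1)[gen_cols],
               tibble::as_tibble(a3)[gen_cols], ignore_attr = TRUE)
})

test_that("assemblage composition matches the configuration", {
  cfg <- sim_config(n = 335, seed = 7, estimate_age = FALSE)
  a <- simulate_assemblage(cfg)
  expect_equal(nrow(a), 335)
  expect_true(all(a$age >= 15))
  # female count within binomial 99% bounds of 161/335
  bounds <- qbinom(c(0.005, 0.995), 335, 161 / 335)
  expect_true(sum(a$sex) >= bounds[1] && sum(a$sex) <= bounds[2])
  expect_setequal(unique(a$period), c("early", "late"))
  # no missingness when switched off
  cfg0 <- sim_config(n = 100, seed = 7, missingness = 0, estimate_age = FALSE)
  a0 <- simulate_assemblage(cfg0)
  expect_false(anyNA(a0[c(names(default_trait_models()),
                          measurement_columns())]))
  expect_error(sim_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(sim_config(age_cap = 10), "age_cap")
})

test_that("stratified simulation with distinct effects is recovered", {
  m <- gompertz_makeham(0.01, 0.005, 0.07)
  set.seed(70)
  mk <- function(n, rho, period) {
    sex <- rbinom(n, 1, 0.5)
    tibble::tibble(age = as.numeric(sample_age(n, m, x = sex, rho = rho)),
                   sex = sex, period = period)
  }
  d <- dplyr::bind_rows(mk(2500, 0, "early"), mk(2500, 0.8, "late"))
  cs <- compare_strata(d, n_starts = 2)
  s <- cs$summary
  expect_lt(abs(s$estimate[s$stratum == "early"] - 0), 0.15)
  expect_lt(abs(s$estimate[s$stratum == "late"] - 0.8), 0.15)
  expect_false(cs$overlap)
})

test_that("the recovery harness aggregates bias, coverage and rejections", {
  cfg <- sim_config(n = 335, rho = 0.07, estimate_age = FALSE,
                    estimate_sex = FALSE, missingness = 0, seed = 88)
  rep <- end_to_end_recovery(cfg, n_reps = 4)
  expect_equal(nrow(rep$replicates), 4)
  expect_named(rep$summary,
               c("basis", "n_reps", "median_bias", "mean_bias", "coverage",
                 "rejection_rate"))
  expect_true(all(rep$replicates$statistic >= 0))
  # estimated-age analysis runs alongside the true-age one
  cfg2 <- sim_config(n = 150, rho = 0.07, seed = 89)
  rep2 <- end_to_end_recovery(cfg2, n_reps = 2, estimated = TRUE)
  expect_setequal(unique(rep2$replicates$basis), c("true", "estimated"))
})
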
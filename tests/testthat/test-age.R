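test_that("stage probabilities follow the cumulative-link construction", {
  tm2 <- transition_model("t", 40, scale = 5)
  p <- stage_probabilities(tm2, 40)
  expect_equal(p$probability, c(0.5, 0.5))
  # far below every threshold: all mass on stage 1
  p_lo <- stage_probabilities(tm2, -200)
  expect_equal(p_lo$probability, c(1, 0), tolerance = 1e-12)
  tm3 <- transition_model("t", c(30, 50), scale = 8)
  p3 <- stage_probabilities(tm3, 40)
  expect_equal(p3$probability, c(0.2227, 0.5546, 0.2227), tolerance = 1e-4)
  expect_equal(sum(p3$probability), 1)
  # probit link uses the normal CDF
  tmp <- transition_model("t", 40, scale = 5, link = "probit")
  expect_equal(stage_probabilities(tmp, 45)$probability[2], pnorm(1))
  expect_error(transition_model("t", c(50, 30), 8), "increasing")
  expect_error(transition_model("t", 40, -1), "scale")
})

test_that("posteriors are normalized and reduce correctly", {
  tm <- transition_model("tr", c(35, 55), scale = 6)
  models <- list(tr = tm)
  up <- age_prior("uniform")
  post <- age_posterior(list(tr = 2), models, up)
  expect_equal(sum(post$density), 1, tolerance = 1e-9)
  # flat prior: posterior proportional to the stage likelihood
  lik <- stage_probabilities(tm, up$grid) |>
    dplyr::filter(stage == 2) |> dplyr::pull(probability)
  expect_equal(post$density, lik / sum(lik), tolerance = 1e-12)
  # no observed traits: posterior equals the prior
  post0 <- age_posterior(list(), models, up)
  expect_equal(post0$density, up$mass)
  # HPD interval lies on the grid and brackets the point estimate
  expect_true(post$interval[["lower"]] >= min(up$grid))
  expect_true(post$interval[["upper"]] <= max(up$grid))
  expect_true(post$interval[["lower"]] <= post$point &&
                post$point <= post$interval[["upper"]])
  expect_error(age_posterior(list(tr = 9), models, up), "invalid")
  expect_error(age_posterior(list(zz = 1), models, up), "no transition model")
})

test_that("an informative attritional prior pulls old-age posteriors down", {
  tm <- transition_model("tr", c(35, 55), scale = 6)
  models <- list(tr = tm)
  up <- age_prior("uniform")
  gm <- age_prior("gompertz_makeham", gompertz_makeham(0.01, 0.005, 0.12))
  old <- list(tr = 3)   # terminal stage, typical of old age
  expect_lt(age_posterior(old, models, gm)$point,
            age_posterior(old, models, up)$point)
})

test_that("multi-trait posteriors are calibrated around the true age", {
  # five informative traits (tight dispersions) with transitions spanning
  # adulthood
  models <- list(
    t1 = transition_model("t1", c(22, 28, 35, 45, 60), scale = 5),
    t2 = transition_model("t2", c(25, 35, 48, 62), scale = 5),
    t3 = transition_model("t3", c(24, 33, 44, 57), scale = 5),
    t4 = transition_model("t4", c(30, 42, 56), scale = 6),
    t5 = transition_model("t5", c(28, 40, 55, 70), scale = 6))
  prior <- age_prior("gompertz_makeham", gompertz_makeham(0.01, 0.005, 0.07))
  set.seed(77)
  n_sim <- 500
  true_age <- 38
  hit <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    obs <- purrr::map(models, function(m) {
      p <- stage_probabilities(m, true_age)$probability
      sample.int(m$n_stages, 1, prob = p)
    })
    post <- age_posterior(obs, models, prior)
    hit[i] <- abs(post$point - true_age) <= 8
  }
  expect_gte(mean(hit), 0.9)
})

test_that("reference fits recover the generating transition model", {
  set.seed(13)
  n <- 2000
  age <- runif(n, 16, 95)
  gen <- transition_model("tr", c(35, 55), scale = 6)
  p <- paleohaz:::.stage_prob_matrix(gen, age)
  st <- paleohaz:::.sample_stages(p, runif(n))
  ref <- tibble::tibble(age = age, tr = st)
  fit <- fit_transition_models(ref)$tr
  expect_lt(max(abs(fit$thresholds - c(35, 55))), 1.5)
  expect_lt(abs(fit$scale - 6), 0.8)
  # duplicating the reference leaves the estimates unchanged
  fit2 <- fit_transition_models(dplyr::bind_rows(ref, ref))$tr
  expect_equal(fit2$thresholds, fit$thresholds, tolerance = 1e-4)
  expect_equal(fit2$scale, fit$scale, tolerance = 1e-4)
  # a single-stage trait cannot be fitted
  expect_error(fit_transition_models(tibble::tibble(age = age, tr = 1)),
               "single stage")
  # a skipped stage label is merged with a warning
  ref_gap <- dplyr::mutate(ref, tr = ifelse(st == 2, 1, st))
  expect_warning(fit_transition_models(ref_gap), "never observed")
})
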
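test_that("sectioning points are per-measurement means over non-missing values", {
  panel <- tibble::tibble(fem_vertical_head_diam = c(40, 44, NA),
                          hum_max_length = c(300, 320, 310))
  pts <- sectioning_points(panel)
  expect_equal(pts$point[pts$measurement == "fem_vertical_head_diam"], 42)
  expect_equal(pts$n_used[pts$measurement == "fem_vertical_head_diam"], 2)
  # an entirely missing measurement is excluded with a warning
  panel$hum_vertical_head_diam <- NA_real_
  expect_warning(pts2 <- sectioning_points(panel), "excluded")
  expect_false("hum_vertical_head_diam" %in% pts2$measurement)
})

test_that("a value exactly at the sectioning point classifies female", {
  panel <- tibble::tibble(id = c("a", "b", "c"),
                          fem_vertical_head_diam = c(42, 42, 42))
  res <- classify_metric(panel)
  expect_true(all(res$call == "female"))
  expect_true(all(res$code == 1))
})

test_that("votes combine by majority, ties are indeterminate", {
  pts <- tibble::tibble(
    measurement = c("fem_vertical_head_diam", "hum_max_length",
                    "hum_epicondylar_breadth"),
    point = c(44, 310, 59), n_used = 10L)
  panel <- tibble::tibble(
    id = 1:3,
    fem_vertical_head_diam = c(46, 46, NA),
    hum_max_length = c(320, 300, 320),
    hum_epicondylar_breadth = c(58, 61, 55))
  res <- classify_metric(panel, pts)
  expect_equal(res$call, c("male", "male", "indeterminate"))
  expect_equal(res$votes_male + res$votes_female, c(3L, 3L, 2L))
})

test_that("shifting one measurement by a constant leaves calls unchanged", {
  set.seed(4)
  panel <- tibble::tibble(
    id = 1:60,
    fem_vertical_head_diam = rnorm(60, 44, 3),
    hum_max_length = rnorm(60, 310, 15))
  base <- classify_metric(panel)
  shifted <- dplyr::mutate(panel, hum_max_length = hum_max_length + 100)
  pts <- sectioning_points(shifted)
  expect_equal(pts$point[pts$measurement == "hum_max_length"],
               sectioning_points(panel)$point[
                 sectioning_points(panel)$measurement == "hum_max_length"] + 100)
  expect_equal(classify_metric(shifted)$call, base$call)
})

test_that("well-separated dimorphism is classified with >= 90% accuracy", {
  set.seed(12)
  n <- 1000
  sex <- rbinom(n, 1, 0.5)
  dim <- default_dimorphism()
  panel <- tibble::tibble(id = seq_len(n))
  for (i in seq_len(nrow(dim))) {
    mu <- ifelse(sex == 1, dim$mean_female[i], dim$mean_male[i])
    panel[[dim$measurement[i]]] <- rnorm(n, mu, dim$sd[i])
  }
  res <- classify_metric(panel)
  acc <- mean(res$code == sex, na.rm = TRUE)
  expect_gte(acc, 0.9)
})

test_that("reconciliation prioritizes post-cranial over skull-only morphology", {
  # disagreement, cranium-only morphology: metric wins
  r1 <- reconcile_sex("female", "male", pelvis_scored = FALSE,
                      cranium_scored = TRUE)
  expect_equal(r1$call, "male")
  expect_equal(r1$source, "metric")
  # disagreement with the pelvis scored: morphology wins
  r2 <- reconcile_sex("male", "female", pelvis_scored = TRUE,
                      cranium_scored = TRUE)
  expect_equal(r2$call, "male")
  expect_equal(r2$source, "morphological")
  # agreement keeps the call
  r3 <- reconcile_sex("female", "female", TRUE, TRUE)
  expect_equal(r3$call, "female")
  expect_equal(r3$code, 1)
  # single determinate input is used as-is; none gives indeterminate
  expect_equal(reconcile_sex("indeterminate", "male", FALSE, TRUE)$call, "male")
  expect_equal(reconcile_sex("female", "indeterminate", TRUE, FALSE)$call,
               "female")
  expect_equal(reconcile_sex("indeterminate", "indeterminate", F, F)$call,
               "indeterminate")
  expect_true(is.na(reconcile_sex("indeterminate", "indeterminate", F, F)$code))
})
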
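# Transition-analysis-style age estimation: per-trait cumulative-link
# models give Pr(stage | age); Bayes' theorem with an informative prior
# gives a posterior over age for an observed stage combination. The module
# is generic — trait set, thresholds and prior all come from configuration,
# not from any particular reference collection.

#' Ordinal-trait transition model
#'
#' A cumulative-link model for one age-progressive skeletal trait with `K`
#' ordered stages: \eqn{\Pr(\text{stage} \ge j+1 \mid a) = g((a - \mu_j)/s)}
#' where \eqn{\mu_1 < \dots < \mu_{K-1}} are mean ages-at-transition,
#' `s` a common dispersion, and `g` the logistic or normal CDF.
#'
#' @param trait Trait label.
#' @param thresholds Strictly increasing mean ages-at-transition (years).
#' @param scale Common dispersion `s` (> 0, years).
#' @param link `"logit"` (default) or `"probit"`.
#' @return An object of class `transition_model`.
#' @examples
#' tm <- transition_model("pubic_symphysis", c(30, 50), scale = 8)
#' stage_probabilities(tm, age = 40)
#' @export
transition_model <- function(trait, thresholds, scale,
                             link = c("logit", "probit")) {
  link <- match.arg(link)
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      anyNA(thresholds) || is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a positive number", call. = FALSE)
  structure(list(trait = trait, thresholds = as.numeric(thresholds),
                 scale = scale, link = link,
                 n_stages = length(thresholds) + 1L),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Transition model `%s`: %d stages, %s link, scale %.3g\n",
              x$trait, x$n_stages, x$link, x$scale))
  cat("  mean ages-at-transition:", paste(signif(x$thresholds, 4),
                                          collapse = ", "), "\n")
  invisible(x)
}

.link_cdf <- function(link) {
  switch(link, logit = stats::plogis, probit = stats::pnorm)
}

# ages x stages probability matrix; rows sum to 1
.stage_prob_matrix <- function(model, ages) {
  g <- .link_cdf(model$link)
  K <- model$n_stages
  # exceedance Pr(stage >= j+1 | a) for j = 1..K-1
  exc <- vapply(model$thresholds,
                function(mu) g((ages - mu) / model$scale),
                numeric(length(ages)))
  exc <- matrix(exc, nrow = length(ages))
  cum <- cbind(1, exc, 0)               # Pr(stage >= j) for j = 1..K+1
  p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  pmax(p, 0)
}

#' Stage probabilities given age
#'
#' @param model A [transition_model()].
#' @param age Calendar age(s) in years; vectorized.
#' @return A tibble with columns `age`, `stage`, `probability`; for each
#'   age the probabilities sum to 1.
#' @export
stage_probabilities <- function(model, age) {
  if (!inherits(model, "transition_model"))
    stop("`model` must be a transition_model", call. = FALSE)
  if (!is.numeric(age) || anyNA(age))
    stop("`age` must be numeric", call. = FALSE)
  p <- .stage_prob_matrix(model, age)
  tidyr::expand_grid(age = age, stage = seq_len(model$n_stages)) |>
    dplyr::arrange(.data$age, .data$stage) |>
    dplyr::mutate(probability = as.vector(t(p)))
}

#' Prior over age-at-death
#'
#' Either uniform on the grid or the death-density of a
#' [gompertz_makeham()] / [gompertz()] model (an informative attritional
#' mortality prior, playing the role of a generalized pre-industrial
#' age-at-death profile). The prior is discretized and normalized on the
#' grid.
#'
#' @param kind `"uniform"` or `"gompertz_makeham"`.
#' @param model Mortality model, required for the informative prior.
#' @param grid Calendar-age grid (default 15 to 110 by 0.25 years).
#' @return An object of class `age_prior` with fields `grid` and `mass`.
#' @export
age_prior <- function(kind = c("uniform", "gompertz_makeham"), model = NULL,
                      grid = seq(15, 110, by = 0.25)) {
  kind <- match.arg(kind)
  if (any(grid < .ENTRY_AGE)) stop("grid must start at or above age 15",
                                   call. = FALSE)
  mass <- if (kind == "uniform") {
    rep(1, length(grid))
  } else {
    if (is.null(model)) stop("informative prior needs `model`", call. = FALSE)
    death_density(model, grid - .ENTRY_AGE)
  }
  mass <- mass / sum(mass)
  structure(list(kind = kind, model = model, grid = grid, mass = mass),
            class = "age_prior")
}

#' Posterior distribution of age-at-death
#'
#' Bayes' theorem on the age grid: posterior mass proportional to
#' prior mass times the product over observed traits of
#' \eqn{\Pr(c_j \mid a)} (traits conditionally independent given age;
#' unobserved traits are simply omitted from the product). Attaches a point
#' estimate (posterior mean by default, mode optionally) and a
#' highest-posterior-density credible interval.
#'
#' @param stages Named list/vector mapping trait label to observed stage;
#'   may be empty, in which case the posterior equals the prior.
#' @param models Named list of [transition_model()]s covering every
#'   observed trait.
#' @param prior An [age_prior()].
#' @param point `"mean"` (default) or `"mode"`.
#' @param level Credible level for the HPD interval.
#' @return An object of class `age_posterior` with fields `grid`,
#'   `density` (normalized mass), `point`, `interval`, `level`.
#' @examples
#' tm <- transition_model("cranial_sutures", c(35, 55), scale = 9)
#' post <- age_posterior(list(cranial_sutures = 2), list(cranial_sutures = tm),
#'                       age_prior("uniform"))
#' post$point
#' @export
age_posterior <- function(stages, models, prior,
                          point = c("mean", "mode"), level = 0.95) {
  point <- match.arg(point)
  stopifnot(inherits(prior, "age_prior"))
  stages <- as.list(stages)
  mass <- prior$mass
  for (trait in names(stages)) {
    m <- models[[trait]]
    if (is.null(m))
      stop(sprintf("no transition model for observed trait `%s`", trait),
           call. = FALSE)
    st <- stages[[trait]]
    if (!st %in% seq_len(m$n_stages))
      stop(sprintf("stage %s invalid for trait `%s` (%d stages)",
                   st, trait, m$n_stages), call. = FALSE)
    mass <- mass * .stage_prob_matrix(m, prior$grid)[, st]
  }
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0)
    stop(sprintf("posterior mass is numerically zero: stage combination {%s} is incompatible with the prior support",
                 paste(sprintf("%s=%s", names(stages), unlist(stages)),
                       collapse = ", ")), call. = FALSE)
  dens <- mass / tot
  pt <- if (point == "mean") sum(prior$grid * dens)
        else prior$grid[which.max(dens)]
  structure(list(grid = prior$grid, density = dens, point = pt,
                 point_type = point,
                 interval = .hpd_interval(prior$grid, dens, level),
                 level = level),
            class = "age_posterior")
}

# HPD by density thresholding: lower the cut until the retained mass
# reaches `level`, then linearly interpolate the grid crossing at the cut
.hpd_interval <- function(grid, mass, level) {
  o <- order(mass, decreasing = TRUE)
  keep <- o[seq_len(which(cumsum(mass[o]) >= level)[1])]
  thr <- min(mass[keep])
  i_lo <- min(keep); i_hi <- max(keep)
  lo <- grid[i_lo]; hi <- grid[i_hi]
  if (i_lo > 1) {
    m0 <- mass[i_lo - 1]; m1 <- mass[i_lo]
    if (m1 > m0) lo <- grid[i_lo - 1] + (thr - m0) / (m1 - m0) *
        (grid[i_lo] - grid[i_lo - 1])
  }
  if (i_hi < length(grid)) {
    m0 <- mass[i_hi]; m1 <- mass[i_hi + 1]
    if (m0 > m1) hi <- grid[i_hi] + (m0 - thr) / (m0 - m1) *
        (grid[i_hi + 1] - grid[i_hi])
  }
  c(lower = lo, upper = hi)
}

#' @export
print.age_posterior <- function(x, ...) {
  cat(sprintf("Age-at-death posterior: %s %.1f y, %d%% HPD [%.1f, %.1f]\n",
              x$point_type, x$point, round(100 * x$level),
              x$interval[["lower"]], x$interval[["upper"]]))
  invisible(x)
}

#' Fit transition models to a known-age reference sample
#'
#' Maximum-likelihood cumulative-link (proportional-odds) fits per trait
#' via [MASS::polr()], re-expressed as mean ages-at-transition and a common
#' dispersion. Stages never observed in the reference are merged into their
#' neighbour (with a warning) before fitting.
#'
#' @param reference Data frame with a known-age column and one integer
#'   stage column per trait.
#' @param age_col Name of the age column.
#' @param traits Trait columns to fit (default: all columns except the age
#'   column).
#' @param link `"logit"` or `"probit"`.
#' @param min_n Minimum reference size.
#' @return Named list of [transition_model()]s.
#' @export
fit_transition_models <- function(reference, age_col = "age", traits = NULL,
                                  link = c("logit", "probit"), min_n = 50) {
  link <- match.arg(link)
  if (!age_col %in% names(reference))
    stop(sprintf("column `%s` not found", age_col), call. = FALSE)
  if (nrow(reference) < min_n)
    stop(sprintf("reference sample needs >= %d individuals", min_n),
         call. = FALSE)
  if (is.null(traits)) traits <- setdiff(names(reference), age_col)
  age <- reference[[age_col]]
  out <- purrr::map(rlang::set_names(traits), function(tr) {
    st <- reference[[tr]]
    ok <- !is.na(st) & !is.na(age)
    st <- st[ok]; a <- age[ok]
    lev <- sort(unique(st))
    if (length(lev) < 2L)
      stop(sprintf("trait `%s` shows a single stage; cannot fit", tr),
           call. = FALSE)
    full <- seq(min(lev), max(lev))
    if (!all(full %in% lev))
      warning(sprintf("trait `%s`: stages {%s} never observed, merged with their lower neighbour",
                      tr, paste(setdiff(full, lev), collapse = ",")),
              call. = FALSE)
    y <- ordered(match(st, lev))          # relabel observed stages 1..K
    if (nlevels(y) == 2L) {
      # two stages: the cumulative-link model is a plain binary regression
      fit <- stats::glm(I(y == "2") ~ a, family = stats::binomial(link))
      b <- unname(stats::coef(fit)[["a"]])
      mu <- -unname(stats::coef(fit)[["(Intercept)"]]) / b
    } else {
      fit <- MASS::polr(y ~ a, method = if (link == "logit") "logistic" else link,
                        Hess = FALSE)
      b <- unname(stats::coef(fit)[["a"]])
      mu <- unname(fit$zeta) / b
    }
    if (b <= 0)
      stop(sprintf("trait `%s` does not progress with age in the reference", tr),
           call. = FALSE)
    transition_model(tr, thresholds = mu, scale = 1 / b, link = link)
  })
  out
}
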
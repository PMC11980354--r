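# Closed-form Gompertz and Gompertz-Makeham hazards with an optional
# proportional-hazards covariate. Age is measured internally as t = years
# since entry at 15 calendar years, so every likelihood conditions on
# survival to 15 implicitly (exact left truncation by construction).

# below this |beta| the exponential terms switch to their constant-hazard
# series limit to avoid catastrophic cancellation in expm1(beta*t)/beta
.BETA_EPS <- 1e-8

# entry age in calendar years; t = age - ENTRY_AGE
.ENTRY_AGE <- 15

#' Gompertz mortality model
#'
#' Constructs a Gompertz baseline hazard \eqn{h(t) = \alpha e^{\beta t}},
#' the classic two-parameter model of senescent mortality: `alpha` is the
#' overall level of mortality due to aging and `beta` the rate at which the
#' risk of death rises with age. Age `t` is measured in years since entry
#' into the adult sample at 15 calendar years.
#'
#' @param alpha Baseline level of senescent mortality (per year, > 0).
#' @param beta Exponential rate of mortality increase with age (per year,
#'   >= 0; values below `1e-8` are treated as the constant-hazard limit).
#' @return An object of class `c("gompertz", "mortality_model")`.
#' @seealso [gompertz_makeham()], [hazard()], [survival_prob()]
#' @examples
#' m <- gompertz(alpha = 0.01, beta = 0.05)
#' hazard(m, t = c(0, 10, 20))
#' @export
gompertz <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta),
            class = c("gompertz", "mortality_model"))
}

#' Gompertz-Makeham mortality model
#'
#' Adds to the Gompertz model a Makeham term `a1`, the constant
#' age-independent risk of adult mortality (accidents, violence, acute
#' infection), giving \eqn{h(t) = \alpha_1 + \alpha_2 e^{\beta t}}.
#'
#' @param a1 Age-independent adult mortality (per year, >= 0).
#' @param a2 Level of the senescent component (per year, > 0).
#' @param beta Rate of mortality increase with age (per year, >= 0).
#' @return An object of class `c("gompertz_makeham", "mortality_model")`.
#' @examples
#' m <- gompertz_makeham(a1 = 0.01, a2 = 0.005, beta = 0.1)
#' hazard(m, t = 10)
#' @export
gompertz_makeham <- function(a1, a2, beta) {
  stopifnot(is.numeric(a1), length(a1) == 1L, is.finite(a1),
            is.numeric(a2), length(a2) == 1L, is.finite(a2),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (a1 < 0) stop("`a1` must be >= 0", call. = FALSE)
  if (a2 <= 0) stop("`a2` must be > 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, beta = beta),
            class = c("gompertz_makeham", "mortality_model"))
}

#' @export
print.mortality_model <- function(x, ...) {
  if (inherits(x, "gompertz")) {
    cat(sprintf("Gompertz hazard: h(t) = %g * exp(%g * t)  [t = years since age 15]\n",
                x$alpha, x$beta))
  } else {
    cat(sprintf("Gompertz-Makeham hazard: h(t) = %g + %g * exp(%g * t)  [t = years since age 15]\n",
                x$a1, x$a2, x$beta))
  }
  invisible(x)
}

.check_model <- function(model) {
  if (!inherits(model, "mortality_model"))
    stop("`model` must be created with gompertz() or gompertz_makeham()",
         call. = FALSE)
  invisible(model)
}

.check_t <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  if (any(t < 0))
    stop("`t` must be >= 0 (years since entry age 15)", call. = FALSE)
  invisible(t)
}

#' Hazard, cumulative hazard, survival and density
#'
#' Closed-form functions of the mortality model at age `t` (years since
#' entry at 15 calendar years). A binary covariate `x` with log-hazard
#' effect `rho` multiplies the whole baseline hazard by
#' \eqn{e^{x\rho}} (proportional hazards), so
#' \eqn{S(t) = \exp(-e^{x\rho} H(t))} and
#' \eqn{f(t) = e^{x\rho} h(t) \exp(-e^{x\rho} H(t))}.
#'
#' @param model A [gompertz()] or [gompertz_makeham()] model.
#' @param t Age in years since entry (>= 0); vectorized.
#' @param x Covariate value (0/1 or any finite numeric), recycled against `t`.
#' @param rho Covariate effect on the log-hazard scale.
#' @return Numeric vector the length of `t` (after recycling with `x`).
#' @examples
#' m <- gompertz_makeham(0.01, 0.005, 0.1)
#' hazard(m, 10)             # 0.01 + 0.005 * exp(1)
#' cumulative_hazard(m, 10)
#' survival_prob(m, 10)
#' death_density(m, 10)
#' @export
hazard <- function(model, t, x = 0, rho = 0) {
  .check_model(model); .check_t(t)
  h <- if (inherits(model, "gompertz")) {
    model$alpha * exp(model$beta * t)
  } else {
    model$a1 + model$a2 * exp(model$beta * t)
  }
  exp(x * rho) * h
}

#' @rdname hazard
#' @export
cumulative_hazard <- function(model, t, x = 0, rho = 0) {
  .check_model(model); .check_t(t)
  H <- if (inherits(model, "gompertz")) {
    .gomp_int(model$alpha, model$beta, t)
  } else {
    model$a1 * t + .gomp_int(model$a2, model$beta, t)
  }
  exp(x * rho) * H
}

# integral of a*exp(b*s) over [0, t], with the b -> 0 series limit
.gomp_int <- function(a, b, t) {
  if (abs(b) < .BETA_EPS) a * t else (a / b) * expm1(b * t)
}

#' @rdname hazard
#' @export
survival_prob <- function(model, t, x = 0, rho = 0) {
  exp(-cumulative_hazard(model, t, x = x, rho = rho))
}

#' @rdname hazard
#' @export
death_density <- function(model, t, x = 0, rho = 0) {
  hazard(model, t, x = x, rho = rho) * survival_prob(model, t, x = x, rho = rho)
}
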
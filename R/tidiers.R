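#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mortality model
#'
#' One row per free parameter with estimate, standard error and confidence
#' interval (Wald by default, at the level stored in the fit).
#'
#' @param x A [fit_mortality()] result.
#' @param level Confidence level (defaults to the fit's).
#' @param ci `"wald"` or `"profile"` (profile applies to `rho` only; other
#'   parameters keep Wald bounds).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.mort_fit <- function(x, level = x$level, ci = c("wald", "profile"), ...) {
  ci <- match.arg(ci)
  rows <- purrr::map(names(x$coef), function(p) {
    int <- tryCatch({
      if (ci == "profile" && p == "rho") profile_ci(x, p, level)
      else wald_ci(x, p, level)
    }, error = function(e) {
      tibble::tibble(parameter = p, estimate = x$coef[[p]],
                     conf.low = NA_real_, conf.high = NA_real_)
    })
    tibble::tibble(term = p, estimate = x$coef[[p]],
                   std.error = x$se[[p]],
                   conf.low = int$conf.low, conf.high = int$conf.high)
  })
  dplyr::bind_rows(rows)
}

#' Glance at a fitted mortality model
#'
#' @param x A [fit_mortality()] result.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `AIC`, `df`, `nobs`,
#'   `converged`, `n_starts`.
#' @export
glance.mort_fit <- function(x, ...) {
  k <- length(x$coef)
  tibble::tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * k,
                 df = k, nobs = x$n_used,
                 converged = x$converged, n_starts = x$n_starts)
}

#' @export
tidy.strata_comparison <- function(x, ...) x$summary
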
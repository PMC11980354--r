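# Maximum-likelihood fitting of Gompertz / Gompertz-Makeham hazards with a
# proportional-hazards covariate, Wald and profile-likelihood intervals, and
# likelihood-ratio model comparison.
#
# Deaths are treated as exactly observed at their point age estimates (no
# censoring, no interval likelihood); every individual contributes
#   x*rho + ln h(t) - exp(x*rho) * H(t)
# with t = calendar age - 15, which makes the 15+ inclusion rule an exact
# left truncation at entry.

# ---- data validation ---------------------------------------------------

.as_fit_data <- function(data, covariate = TRUE,
                         age_col = "age", sex_col = "sex") {
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("`data` must be a nonempty data frame", call. = FALSE)
  if (!age_col %in% names(data))
    stop(sprintf("column `%s` not found in `data`", age_col), call. = FALSE)
  age <- data[[age_col]]
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age)))
    stop("ages must be finite numeric", call. = FALSE)
  if (any(age < .ENTRY_AGE))
    stop(sprintf("all ages must be >= %d years (adult entry age)", .ENTRY_AGE),
         call. = FALSE)
  x <- rep(0, length(age))
  if (covariate) {
    if (!sex_col %in% names(data))
      stop(sprintf("column `%s` not found in `data`", sex_col), call. = FALSE)
    x <- data[[sex_col]]
    if (anyNA(x) || !all(x %in% c(0, 1)))
      stop("covariate must be coded 0/1 with no missing values", call. = FALSE)
  }
  tibble::tibble(t = age - .ENTRY_AGE, x = as.numeric(x))
}

# order-invariant fingerprints of the data used in a fit, so that lrt()
# can refuse comparisons across different data; ages are always compared,
# covariate values only between two covariate fits (the reduced model never
# reads them)
.data_digest <- function(df) {
  o <- order(df$t, df$x)
  list(t = rlang::hash(round(df$t[o], 10)),
       tx = rlang::hash(list(round(df$t[o], 10), df$x[o])))
}

# ---- log-likelihood ----------------------------------------------------

#' Log-likelihood of a proportional-hazards mortality model
#'
#' Sum over individuals of
#' \eqn{x_i\rho + \ln h(t_i) - e^{x_i\rho} H(t_i)} with
#' \eqn{t_i = } age \eqn{- 15}: the exact-death log-likelihood of the model
#' left-truncated at the 15-year entry age.
#'
#' @param data Data frame with an age column (calendar years, >= 15) and,
#'   when `rho` is used, a 0/1 covariate column.
#' @param model A [gompertz()] or [gompertz_makeham()] baseline.
#' @param rho Covariate effect on the log-hazard scale (default 0).
#' @param age_col,sex_col Column names (defaults `"age"`, `"sex"`).
#' @return The scalar log-likelihood.
#' @examples
#' d <- tibble::tibble(age = c(35, 50), sex = c(0, 1))
#' log_likelihood(d, gompertz_makeham(0.01, 0.005, 0.1), rho = 0.2)
#' @export
log_likelihood <- function(data, model, rho = 0,
                           age_col = "age", sex_col = "sex") {
  covariate <- sex_col %in% names(data)
  df <- .as_fit_data(data, covariate = covariate,
                     age_col = age_col, sex_col = sex_col)
  .loglik_tx(df$t, df$x, model, rho)
}

.loglik_tx <- function(t, x, model, rho) {
  sum(x * rho + log(hazard(model, t)) -
        exp(x * rho) * cumulative_hazard(model, t))
}

# ---- reparameterisation ------------------------------------------------
# positive parameters are optimised on the log scale; the Makeham level a1
# uses softplus so the optimiser can push it arbitrarily close to 0

.softplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))
.inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))
.dsoftplus <- function(u) stats::plogis(u)

.par_names <- function(family, covariate) {
  base <- if (family == "gompertz") c("alpha", "beta") else c("a1", "a2", "beta")
  if (covariate) c(base, "rho") else base
}

# transformed -> natural scale
.theta_to_coef <- function(theta, family, covariate) {
  if (family == "gompertz") {
    cf <- c(alpha = exp(theta[[1]]), beta = exp(theta[[2]]))
  } else {
    cf <- c(a1 = .softplus(theta[[1]]), a2 = exp(theta[[2]]),
            beta = exp(theta[[3]]))
  }
  if (covariate) cf <- c(cf, rho = theta[[length(theta)]])
  cf
}

.coef_to_theta <- function(cf, family, covariate) {
  if (family == "gompertz") {
    th <- c(log(cf[["alpha"]]), log(cf[["beta"]]))
  } else {
    th <- c(.inv_softplus(max(cf[["a1"]], 1e-12)), log(cf[["a2"]]),
            log(cf[["beta"]]))
  }
  if (covariate) th <- c(th, cf[["rho"]])
  th
}

# jacobian diag d(natural)/d(transformed) at theta
.theta_jacobian <- function(theta, family, covariate) {
  if (family == "gompertz") {
    j <- c(exp(theta[[1]]), exp(theta[[2]]))
  } else {
    j <- c(.dsoftplus(theta[[1]]), exp(theta[[2]]), exp(theta[[3]]))
  }
  if (covariate) j <- c(j, 1)
  j
}

.build_model <- function(cf, family) {
  if (family == "gompertz") gompertz(cf[["alpha"]], cf[["beta"]])
  else gompertz_makeham(cf[["a1"]], cf[["a2"]], cf[["beta"]])
}

# negative log-likelihood on the transformed scale; large finite penalty on
# numerical failure so optim() can recover
.make_negll <- function(t, x, family, covariate) {
  function(theta) {
    cf <- .theta_to_coef(theta, family, covariate)
    rho <- if (covariate) cf[["rho"]] else 0
    m <- tryCatch(.build_model(cf, family), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- .loglik_tx(t, x, m, rho)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# moment-based starting values: Gompertz death ages behave like a Gumbel
# variate with scale 1/beta, so sd(t) pins beta; the level is then set so
# the median age satisfies H(median) = ln 2
.moment_start <- function(t, family, covariate) {
  s <- stats::sd(t)
  if (!is.finite(s) || s < 1) s <- 10
  beta0 <- min(max(pi / (s * sqrt(6)), 0.01), 0.3)
  med <- max(stats::median(t), 1)
  lev <- log(2) * beta0 / expm1(beta0 * med)
  cf <- if (family == "gompertz") {
    c(alpha = lev, beta = beta0)
  } else {
    c(a1 = 0.3 * log(2) / med, a2 = max(lev * 0.7, 1e-6), beta = beta0)
  }
  if (covariate) cf <- c(cf, rho = 0)
  .coef_to_theta(cf, family, covariate)
}

# ---- main fitting routine ----------------------------------------------

#' Fit a mortality model by maximum likelihood
#'
#' Fits a Gompertz or Gompertz-Makeham baseline hazard to point
#' age-at-death data, optionally with a binary covariate (e.g., sex coded
#' 0 = male / 1 = female) acting multiplicatively on the whole hazard
#' (proportional-hazards specification, effect `rho` on the log scale).
#'
#' Optimisation runs on an unconstrained reparameterisation (log scale for
#' positive parameters, softplus for the Makeham level so it may approach
#' zero) with `n_starts` jittered moment-based starting points; the best
#' optimum is kept. Standard errors come from the numerically differenced
#' Hessian on the transformed scale, mapped to the natural scale by the
#' delta method.
#'
#' @param data Data frame with columns `age` (calendar years >= 15) and,
#'   when `covariate = TRUE`, `sex` (0/1).
#' @param family `"gompertz_makeham"` (default) or `"gompertz"`.
#' @param covariate Include the proportional-hazards covariate?
#' @param level Confidence level for the intervals reported by [tidy()].
#' @param n_starts Number of multistart optimisations (first start
#'   unjittered, the rest jittered 20% on the transformed scale).
#' @param seed Seed for the start-point jitter only; the caller's RNG state
#'   is left untouched.
#' @param min_n Minimum number of individuals required.
#' @param age_col,sex_col Column names in `data`.
#' @param control Passed to [stats::optim()] (BFGS); a tight `reltol` is
#'   set by default.
#' @return An object of class `mort_fit`: coefficients, standard errors,
#'   covariance, log-likelihood, convergence flag, and the (t, x) data used
#'   (kept for profile intervals and nested-model checks).
#' @examples
#' set.seed(1)
#' d <- simulate_assemblage(sim_config(n = 300, seed = 7))
#' fit <- fit_mortality(d, n_starts = 3)
#' tidy(fit)
#' @export
fit_mortality <- function(data,
                          family = c("gompertz_makeham", "gompertz"),
                          covariate = TRUE,
                          level = 0.95,
                          n_starts = 10,
                          seed = 20250409,
                          min_n = 10,
                          age_col = "age", sex_col = "sex",
                          control = list()) {
  family <- match.arg(family)
  df <- .as_fit_data(data, covariate = covariate,
                     age_col = age_col, sex_col = sex_col)
  if (nrow(df) < min_n)
    stop(sprintf("need at least %d individuals (got %d)", min_n, nrow(df)),
         call. = FALSE)
  if (covariate && length(unique(df$x)) < 2L)
    stop("covariate has a single level; its effect is unidentifiable",
         call. = FALSE)

  negll <- .make_negll(df$t, df$x, family, covariate)
  theta0 <- .moment_start(df$t, family, covariate)
  control <- utils::modifyList(list(reltol = 1e-12, maxit = 500), control)

  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1L) theta0
      else theta0 * (1 + stats::runif(length(theta0), -0.2, 0.2))
    })
  })

  best <- NULL
  for (th in starts) {
    opt <- tryCatch(
      stats::optim(th, negll, method = "BFGS", control = control),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimisation failed from every start", call. = FALSE)

  theta_hat <- best$par
  cf <- .theta_to_coef(theta_hat, family, covariate)
  names(cf) <- .par_names(family, covariate)
  converged <- best$convergence == 0L

  # delta-method covariance on the natural scale
  se <- se_trans <- rep(NA_real_, length(cf))
  vcov_nat <- NULL
  hess <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
  if (!is.null(hess)) {
    cov_t <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_t) && all(is.finite(diag(cov_t))) &&
        all(diag(cov_t) > 0)) {
      J <- diag(.theta_jacobian(theta_hat, family, covariate),
                nrow = length(theta_hat))
      vcov_nat <- J %*% cov_t %*% J
      dimnames(vcov_nat) <- list(names(cf), names(cf))
      se <- sqrt(diag(vcov_nat))
      se_trans <- sqrt(diag(cov_t))
    } else {
      warning("Hessian is singular; standard errors reported as missing",
              call. = FALSE)
    }
  } else {
    warning("Hessian computation failed; standard errors reported as missing",
            call. = FALSE)
  }
  names(se) <- names(se_trans) <- names(cf)

  structure(list(
    family = family,
    covariate = covariate,
    coef = cf,
    se = se,
    se_trans = se_trans,
    theta = theta_hat,
    vcov = vcov_nat,
    loglik = -best$value,
    converged = converged,
    n_used = nrow(df),
    n_starts = n_starts,
    level = level,
    seed = seed,
    data = df,
    digest = .data_digest(df),
    model = .build_model(cf, family)
  ), class = "mort_fit")
}

#' @export
print.mort_fit <- function(x, ...) {
  cat(sprintf("%s hazard fit%s, n = %d, logLik = %.4f%s\n",
              if (x$family == "gompertz") "Gompertz" else "Gompertz-Makeham",
              if (x$covariate) " with PH covariate" else "",
              x$n_used, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
logLik.mort_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef),
            nobs = object$n_used, class = "logLik")
}

#' @export
coef.mort_fit <- function(object, ...) object$coef

# ---- confidence intervals ----------------------------------------------

#' Wald confidence interval for a fitted parameter
#'
#' For `rho` the interval is symmetric on its own scale; for the positive
#' baseline parameters it is built on the unconstrained (log / softplus)
#' scale and back-transformed, so the bounds respect positivity.
#'
#' @param fit A [fit_mortality()] result with valid standard errors.
#' @param parameter Parameter name (default `"rho"`).
#' @param level Confidence level in `[0, 1)` plus the degenerate `level = 0`.
#' @return A tibble with `parameter`, `estimate`, `conf.low`, `conf.high`,
#'   `level`, `method`.
#' @export
wald_ci <- function(fit, parameter = "rho", level = fit$level) {
  stopifnot(inherits(fit, "mort_fit"))
  if (!parameter %in% names(fit$coef))
    stop(sprintf("parameter `%s` not in fit", parameter), call. = FALSE)
  i <- match(parameter, names(fit$coef))
  if (is.na(fit$se[[i]]))
    stop("standard error unavailable for this parameter", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  est <- fit$coef[[i]]
  if (parameter == "rho") {
    lo <- est - z * fit$se[[i]]
    hi <- est + z * fit$se[[i]]
  } else {
    th <- fit$theta[[i]]
    s <- fit$se_trans[[i]]
    back <- if (fit$family != "gompertz" && parameter == "a1") .softplus else exp
    lo <- back(th - z * s)
    hi <- back(th + z * s)
  }
  tibble::tibble(parameter = parameter, estimate = est,
                 conf.low = lo, conf.high = hi,
                 level = level, method = "wald")
}

#' Profile-likelihood confidence interval
#'
#' Inverts the likelihood-ratio test: the endpoints are where the profiled
#' log-likelihood has dropped by half the chi-square(1) quantile from its
#' maximum, found by bisection. Unlike the Wald interval it is not forced
#' to be symmetric.
#'
#' @param fit A converged [fit_mortality()] result.
#' @param parameter Profiled parameter (currently `"rho"`).
#' @param level Confidence level.
#' @param max_widen Widest bracket searched, in Wald standard errors; an
#'   endpoint not found inside it is reported as `-Inf`/`Inf`.
#' @return A tibble like [wald_ci()]'s with `method = "profile"`.
#' @export
profile_ci <- function(fit, parameter = "rho", level = fit$level,
                       max_widen = 12) {
  stopifnot(inherits(fit, "mort_fit"))
  if (parameter != "rho")
    stop("profile intervals are implemented for `rho` only", call. = FALSE)
  if (!fit$covariate)
    stop("fit has no covariate to profile", call. = FALSE)
  i <- match("rho", names(fit$coef))
  rho_hat <- fit$coef[[i]]
  step <- if (is.finite(fit$se[[i]]) && fit$se[[i]] > 0) fit$se[[i]] else 0.5
  crit <- stats::qchisq(level, 1) / 2
  ll_max <- fit$loglik

  # profiled log-likelihood: maximise over baseline parameters at fixed rho
  base_theta <- fit$theta[-length(fit$theta)]
  t <- fit$data$t; x <- fit$data$x; family <- fit$family
  prof <- function(rho) {
    negb <- function(thb) {
      th <- c(thb, rho)
      .make_negll(t, x, family, TRUE)(th)
    }
    opt <- tryCatch(
      stats::optim(base_theta, negb, method = "BFGS",
                   control = list(reltol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) return(-Inf)
    -opt$value
  }
  drop_fun <- function(rho) (ll_max - prof(rho)) - crit

  find_side <- function(dir) {
    lo <- rho_hat
    hi <- NULL
    for (k in seq_len(ceiling(max_widen))) {
      cand <- rho_hat + dir * k * step
      if (drop_fun(cand) > 0) { hi <- cand; break }
      lo <- cand
    }
    if (is.null(hi)) return(dir * Inf)
    stats::uniroot(drop_fun, lower = min(lo, hi), upper = max(lo, hi),
                   tol = 1e-6)$root
  }

  lo <- if (level == 0) rho_hat else find_side(-1)
  hi <- if (level == 0) rho_hat else find_side(+1)
  if (!is.finite(lo) || !is.finite(hi))
    warning("profile did not drop by the chi-square quantile inside the bracket; unbounded endpoint reported",
            call. = FALSE)
  tibble::tibble(parameter = "rho", estimate = rho_hat,
                 conf.low = lo, conf.high = hi,
                 level = level, method = "profile")
}

# ---- likelihood-ratio machinery ----------------------------------------

#' Upper tail of the chi-square distribution
#'
#' Survival function of the chi-square distribution, used to convert a
#' likelihood-ratio statistic into a p-value.
#'
#' @param stat Nonnegative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @examples
#' chisq_upper_tail(0.51, 1)  # ~0.475
#' @export
chisq_upper_tail <- function(stat, df = 1) {
  if (!is.numeric(stat) || anyNA(stat) || any(stat < 0))
    stop("`stat` must be >= 0", call. = FALSE)
  if (!is.numeric(df) || any(df < 1))
    stop("`df` must be >= 1", call. = FALSE)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of nested mortality models
#'
#' Computes `2 * (logLik(full) - logLik(reduced))` (clamped at zero if the
#' nested optimum marginally exceeds the full one) and refers it to a
#' chi-square distribution with degrees of freedom equal to the difference
#' in free parameters — 1 when the full model adds the sex covariate.
#' Refuses to compare fits made on different data.
#'
#' @param fit_full,fit_reduced Nested [fit_mortality()] results on the same
#'   data (covariate on vs off, or Gompertz-Makeham vs Gompertz baseline).
#' @param alpha Significance threshold for the decision flag (default 0.1).
#' @return An `lrt_result`: a one-row tibble with `statistic`, `df`,
#'   `p.value`, `alpha`, `significant`.
#' @export
lrt <- function(fit_full, fit_reduced, alpha = 0.1) {
  stopifnot(inherits(fit_full, "mort_fit"), inherits(fit_reduced, "mort_fit"))
  same <- identical(fit_full$digest$t, fit_reduced$digest$t) &&
    (!(fit_full$covariate && fit_reduced$covariate) ||
       identical(fit_full$digest$tx, fit_reduced$digest$tx))
  if (!same || fit_full$n_used != fit_reduced$n_used)
    stop("fits were made on different data; LRT is not meaningful",
         call. = FALSE)
  df <- length(fit_full$coef) - length(fit_reduced$coef)
  nested <- df >= 1 &&
    ((fit_full$family == fit_reduced$family &&
        fit_full$covariate && !fit_reduced$covariate) ||
       (fit_full$family == "gompertz_makeham" &&
          fit_reduced$family == "gompertz" &&
          fit_full$covariate == fit_reduced$covariate))
  if (!nested)
    stop("`fit_reduced` is not nested in `fit_full`", call. = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  out <- tibble::tibble(
    statistic = stat, df = df,
    p.value = chisq_upper_tail(stat, df),
    alpha = alpha,
    significant = chisq_upper_tail(stat, df) < alpha)
  class(out) <- c("lrt_result", class(out))
  out
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: statistic = %.4f (df = %d), p = %.4f\n",
              x$statistic, x$df, x$p.value))
  cat(if (x$significant)
    sprintf("Improvement significant at alpha = %g.\n", x$alpha)
    else
      sprintf("Failed to indicate an improvement at alpha = %g (this does not demonstrate the absence of an effect).\n",
              x$alpha))
  invisible(x)
}

# ---- stratified comparison ---------------------------------------------

#' Compare the covariate effect across strata
#'
#' Fits the proportional-hazards model independently within each stratum
#' (e.g., early vs late medieval period) and reports, per stratum, the
#' covariate effect with its confidence interval, whether that interval
#' spans zero, and whether the strata's intervals mutually overlap.
#' Overlapping intervals are read as *failing to indicate* a difference
#' between strata, never as demonstrating its absence.
#'
#' @param data Data frame with `age`, `sex` and the stratum column.
#' @param strata Name of the stratum column (default `"period"`).
#' @param level Confidence level for the per-stratum intervals.
#' @param alpha Significance threshold carried into the report.
#' @param ci Interval type: `"wald"` (default) or `"profile"`.
#' @param min_n Strata smaller than this are flagged and skipped.
#' @param ... Passed to [fit_mortality()] (family, n_starts, seed, ...).
#' @return A `strata_comparison`: list with `summary` (tibble: stratum, n,
#'   estimate, conf.low, conf.high, spans_zero, fitted), `fits`,
#'   `overlap` (logical, NA when fewer than two strata were fitted),
#'   `level`.
#' @export
compare_strata <- function(data, strata = "period", level = 0.95,
                           alpha = 0.1, ci = c("wald", "profile"),
                           min_n = 10, ...) {
  ci <- match.arg(ci)
  if (!strata %in% names(data))
    stop(sprintf("column `%s` not found in `data`", strata), call. = FALSE)
  groups <- split(data, data[[strata]])
  fits <- list()
  rows <- purrr::imap(groups, function(g, label) {
    if (nrow(g) < min_n || length(unique(g$sex)) < 2L) {
      return(tibble::tibble(stratum = label, n = nrow(g),
                            estimate = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, spans_zero = NA,
                            fitted = FALSE))
    }
    f <- fit_mortality(g, level = level, ...)
    fits[[label]] <<- f
    int <- if (ci == "wald") wald_ci(f, "rho", level) else profile_ci(f, "rho", level)
    tibble::tibble(stratum = label, n = nrow(g),
                   estimate = int$estimate,
                   conf.low = int$conf.low, conf.high = int$conf.high,
                   spans_zero = int$conf.low <= 0 & int$conf.high >= 0,
                   fitted = TRUE)
  })
  summary <- dplyr::bind_rows(rows)
  done <- summary[summary$fitted, , drop = FALSE]
  overlap <- if (nrow(done) >= 2) {
    max(done$conf.low) <= min(done$conf.high)
  } else NA
  structure(list(summary = summary, fits = fits, overlap = overlap,
                 level = level, alpha = alpha, ci = ci),
            class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat(sprintf("Covariate effect by stratum (%d%% %s intervals)\n",
              round(100 * x$level), x$ci))
  print(x$summary, ...)
  if (is.na(x$overlap)) {
    cat("Fewer than two fitted strata; no between-stratum comparison made.\n")
  } else if (x$overlap) {
    cat("The intervals overlap: the analysis failed to indicate a significant difference between strata (which is not evidence of no difference).\n")
  } else {
    cat("The intervals do not overlap, indicating a difference in the covariate effect between strata.\n")
  }
  invisible(x)
}
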
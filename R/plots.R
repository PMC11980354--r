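#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted mortality model
#'
#' Hazard or survival curves over calendar age, one curve per covariate
#' level when the fit includes one.
#'
#' @param object A [fit_mortality()] result.
#' @param type `"hazard"` or `"survival"`.
#' @param max_age Upper calendar age for the curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mort_fit <- function(object, type = c("hazard", "survival"),
                              max_age = 90, ...) {
  type <- match.arg(type)
  ages <- seq(.ENTRY_AGE, max_age, by = 0.5)
  levels <- if (object$covariate) c(0, 1) else 0
  rho <- if (object$covariate) object$coef[["rho"]] else 0
  fn <- if (type == "hazard") hazard else survival_prob
  df <- purrr::map(levels, function(x) {
    tibble::tibble(age = ages, x = factor(x, levels = c(0, 1),
                                          labels = c("male (0)", "female (1)")),
                   value = fn(object$model, ages - .ENTRY_AGE, x = x, rho = rho))
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value,
                                        colour = .data$x)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Calendar age (years)",
                  y = if (type == "hazard") "Hazard (per year)"
                  else "Survival from age 15",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (type == "hazard") p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an age-at-death posterior
#'
#' Posterior density over the age grid with the HPD interval shaded and
#' the point estimate marked.
#'
#' @param object An [age_posterior()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_posterior <- function(object, ...) {
  step <- mean(diff(object$grid))
  df <- tibble::tibble(age = object$grid, density = object$density / step)
  shade <- dplyr::filter(df, .data$age >= object$interval[["lower"]],
                         .data$age <= object$interval[["upper"]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$density)) +
    ggplot2::geom_area(data = shade, fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$point, linetype = "dashed") +
    ggplot2::labs(x = "Age-at-death (years)", y = "Posterior density",
                  subtitle = sprintf("%s %.1f y, %d%% HPD [%.1f, %.1f]",
                                     object$point_type, object$point,
                                     round(100 * object$level),
                                     object$interval[["lower"]],
                                     object$interval[["upper"]])) +
    ggplot2::theme_minimal()
}

#' Plot a simulated assemblage
#'
#' Age-at-death distribution by sex.
#'
#' @param object A [simulate_assemblage()] result.
#' @param binwidth Histogram bin width in years.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assemblage <- function(object, binwidth = 5, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      sex = factor(.data$sex, levels = c(0, 1),
                                   labels = c("male (0)", "female (1)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, fill = .data$sex)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = .ENTRY_AGE,
                            position = "identity", alpha = 0.55) +
    ggplot2::labs(x = "Age-at-death (years)", y = "Individuals",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery study
#'
#' Distribution of the estimated covariate effect across replicates, by
#' analysis basis, with the generating value marked.
#'
#' @param object An [end_to_end_recovery()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$rho_hat, fill = .data$basis)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.55) +
    ggplot2::geom_vline(xintercept = object$config$rho, linetype = "dashed") +
    ggplot2::labs(x = expression(hat(rho)), y = "Replicates", fill = NULL) +
    ggplot2::theme_minimal()
}
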
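# Sample-specific sectioning-point metric sex classification and the
# reconciliation rule against an externally supplied morphological call.
# The morphological estimate (e.g., from pelvis/cranium trait scoring fed
# through an external classifier) is consumed as a given categorical
# column, never computed here.

#' Standard post-cranial measurement columns
#'
#' The six humeral and femoral measurements (mm) used for metric sex
#' classification: humeral epicondylar breadth, maximum length, vertical
#' and transverse head diameters; femoral vertical head diameter and
#' bicondylar width.
#'
#' @return Character vector of canonical column names.
#' @export
measurement_columns <- function() {
  c("hum_epicondylar_breadth", "hum_max_length",
    "hum_vertical_head_diam", "hum_transverse_head_diam",
    "fem_vertical_head_diam", "fem_bicondylar_width")
}

#' Sample-specific sectioning points
#'
#' The sectioning point of each measurement is its arithmetic mean over the
#' non-missing values in the assemblage. Measurements with fewer than two
#' usable values are excluded with a warning.
#'
#' @param panel Data frame of per-individual measurements (mm); missing
#'   values allowed.
#' @param measurements Columns to use (default: whichever of
#'   [measurement_columns()] are present).
#' @return A tibble with `measurement`, `point`, `n_used`.
#' @export
sectioning_points <- function(panel, measurements = NULL) {
  if (is.null(measurements))
    measurements <- intersect(measurement_columns(), names(panel))
  if (length(measurements) == 0L)
    stop("no measurement columns found", call. = FALSE)
  rows <- purrr::map(measurements, function(m) {
    v <- panel[[m]]
    v <- v[!is.na(v)]
    if (any(v <= 0)) stop(sprintf("non-positive values in `%s`", m),
                          call. = FALSE)
    if (length(v) < 2L) {
      warning(sprintf("measurement `%s` has < 2 values; excluded", m),
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(measurement = m, point = mean(v), n_used = length(v))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    stop("no measurement has >= 2 non-missing values", call. = FALSE)
  out
}

#' Metric sex classification by sectioning points
#'
#' Each available measurement votes male if strictly greater than its
#' sectioning point and female if equal to or below it; the combined call
#' is the majority of votes, with an exact tie (or no usable measurement)
#' returned as indeterminate.
#'
#' @param panel Data frame with an `id` column (optional) and measurement
#'   columns in mm.
#' @param points Sectioning points as returned by [sectioning_points()];
#'   computed from `panel` itself when `NULL`.
#' @return A tibble with `id`, `votes_male`, `votes_female`, `call`
#'   (`"male"`, `"female"`, `"indeterminate"`), `code` (0 male / 1 female,
#'   `NA` when indeterminate), `source = "metric"`.
#' @export
classify_metric <- function(panel, points = NULL) {
  if (is.null(points)) points <- sectioning_points(panel)
  use <- intersect(points$measurement, names(panel))
  if (length(use) == 0L)
    stop("no measurement in `panel` has a sectioning point", call. = FALSE)
  pt <- stats::setNames(points$point, points$measurement)[use]
  vals <- as.matrix(panel[, use, drop = FALSE])
  male_votes <- rowSums(sweep(vals, 2, pt, ">"), na.rm = TRUE)
  female_votes <- rowSums(sweep(vals, 2, pt, "<="), na.rm = TRUE)
  call <- dplyr::case_when(
    male_votes + female_votes == 0 ~ "indeterminate",
    male_votes > female_votes ~ "male",
    female_votes > male_votes ~ "female",
    TRUE ~ "indeterminate")
  tibble::tibble(
    id = if ("id" %in% names(panel)) panel$id else seq_len(nrow(panel)),
    votes_male = as.integer(male_votes),
    votes_female = as.integer(female_votes),
    call = call,
    code = dplyr::case_when(call == "male" ~ 0, call == "female" ~ 1,
                            TRUE ~ NA_real_),
    source = "metric")
}

#' Reconcile morphological and metric sex estimates
#'
#' Agreement keeps the shared call. On disagreement, the metric
#' (post-cranial) call wins when only cranial morphological traits were
#' scored; a pelvis-backed morphological call wins otherwise. If only one
#' estimate is determinate it is used as-is; if neither is, the result is
#' indeterminate.
#'
#' @param morph,metric Character vectors of `"male"` / `"female"` /
#'   `"indeterminate"` calls (recycled to a common length).
#' @param pelvis_scored,cranium_scored Logical: which morphological
#'   elements were scored.
#' @return A tibble with `call`, `code`, `source` (`"reconciled"`,
#'   `"morphological"`, or `"metric"`).
#' @export
reconcile_sex <- function(morph, metric, pelvis_scored, cranium_scored) {
  n <- max(length(morph), length(metric), length(pelvis_scored),
           length(cranium_scored))
  morph <- rep_len(as.character(morph), n)
  metric <- rep_len(as.character(metric), n)
  pelvis_scored <- rep_len(as.logical(pelvis_scored), n)
  cranium_scored <- rep_len(as.logical(cranium_scored), n)
  ok <- c("male", "female", "indeterminate")
  if (!all(morph %in% ok) || !all(metric %in% ok))
    stop('calls must be "male", "female" or "indeterminate"', call. = FALSE)

  morph_det <- morph != "indeterminate"
  metric_det <- metric != "indeterminate"
  call <- dplyr::case_when(
    !morph_det & !metric_det ~ "indeterminate",
    !morph_det ~ metric,
    !metric_det ~ morph,
    morph == metric ~ morph,
    # disagreement: post-cranial metric beats skull-only morphology,
    # pelvis-backed morphology beats metric
    cranium_scored & !pelvis_scored ~ metric,
    TRUE ~ morph)
  source <- dplyr::case_when(
    !morph_det & !metric_det ~ "reconciled",
    !morph_det ~ "metric",
    !metric_det ~ "morphological",
    morph == metric ~ "reconciled",
    cranium_scored & !pelvis_scored ~ "metric",
    TRUE ~ "morphological")
  tibble::tibble(
    call = call,
    code = dplyr::case_when(call == "male" ~ 0, call == "female" ~ 1,
                            TRUE ~ NA_real_),
    source = source)
}
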
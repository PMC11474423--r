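# Deterministic severity-score calculators. All functions are vectorised
# over their inputs and propagate NA (a missing component makes the score
# missing rather than silently scoring 0).

.motor_levels <- c("spontaneous_or_verbal", "pain_only", "none")
.motor_points <- c(spontaneous_or_verbal = 6L, pain_only = 3L, none = 1L)

.check_range <- function(x, lo, hi, name, integer = FALSE) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(name, " out of range [", lo, ", ", hi, "]: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  if (integer) {
    nonint <- !is.na(x) & x != floor(x)
    if (any(nonint)) {
      stop(name, " must be integer-valued: ",
           paste(utils::head(x[nonint], 3), collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

.check_vitals <- function(temperature, heart_rate, resp_rate, sbp, spo2) {
  .check_range(temperature, 25, 45, "temperature")
  .check_range(heart_rate, 0, 300, "heart_rate")
  .check_range(resp_rate, 0, 90, "resp_rate")
  .check_range(sbp, 0, 300, "sbp")
  .check_range(spo2, 0, 100, "spo2")
  invisible(NULL)
}

#' Modified Glasgow Coma Scale
#'
#' A simplified GCS for settings where the motor examination records only
#' whether the patient moves spontaneously (or to a verbal request), only to
#' pain, or not at all: those three categories score 6, 3 and 1 motor points
#' respectively. Eye (1-4) and verbal (1-5) responses are scored as in the
#' conventional GCS, so the total ranges 3-15 but cannot take values that
#' would require motor points outside \{1, 3, 6\}.
#'
#' @param eye_response integer 1-4.
#' @param verbal_response integer 1-5.
#' @param motor_category one of `"spontaneous_or_verbal"`, `"pain_only"`,
#'   `"none"`.
#' @return integer GCS total in 3-15; `NA` where any component is missing.
#' @examples
#' modified_gcs(4, 5, "spontaneous_or_verbal")  # 15, fully alert
#' modified_gcs(1, 1, "none")                   # 3, unresponsive
#' @export
modified_gcs <- function(eye_response, verbal_response, motor_category) {
  .check_range(eye_response, 1, 4, "eye_response", integer = TRUE)
  .check_range(verbal_response, 1, 5, "verbal_response", integer = TRUE)
  motor_category <- as.character(motor_category)
  bad <- !is.na(motor_category) & !(motor_category %in% .motor_levels)
  if (any(bad)) {
    stop("motor_category must be one of ",
         paste(.motor_levels, collapse = ", "), "; got '",
         motor_category[bad][1], "'", call. = FALSE)
  }
  as.integer(eye_response) + as.integer(verbal_response) +
    unname(.motor_points[motor_category])
}

#' Convert a modified GCS total to the AVPU scale
#'
#' The AVPU consciousness level needed for MEWS is derived from the GCS by
#' the standard teaching correspondence: Alert = GCS 15, responds to Voice =
#' GCS 9-14, responds to Pain = GCS 4-8, Unresponsive = GCS 3.
#'
#' @param gcs integer GCS total in 3-15 (e.g. from [modified_gcs()]).
#' @return character vector with levels `"A"`, `"V"`, `"P"`, `"U"`.
#' @export
gcs_to_avpu <- function(gcs) {
  .check_range(gcs, 3, 15, "gcs", integer = TRUE)
  out <- rep(NA_character_, length(gcs))
  out[!is.na(gcs) & gcs == 15] <- "A"
  out[!is.na(gcs) & gcs >= 9 & gcs <= 14] <- "V"
  out[!is.na(gcs) & gcs >= 4 & gcs <= 8] <- "P"
  out[!is.na(gcs) & gcs == 3] <- "U"
  out
}

#' Modified Early Warning Score (MEWS)
#'
#' Sums the component points of [mews_band_table()] for temperature, heart
#' rate, respiratory rate, systolic blood pressure and AVPU level.
#'
#' @param temperature body temperature, degrees C (0.1 resolution).
#' @param heart_rate heart rate, beats per minute.
#' @param resp_rate respiratory rate, breaths per minute.
#' @param sbp systolic blood pressure, mmHg.
#' @param avpu consciousness level `"A"`, `"V"`, `"P"` or `"U"` (see
#'   [gcs_to_avpu()]).
#' @param table score band table; defaults to [mews_band_table()].
#' @return integer MEWS total (0-14 under the default table); `NA` where any
#'   component is missing.
#' @examples
#' score_mews(38.0, 99, 20, 117, avpu = "A")  # 1 (respiratory-rate band)
#' @export
score_mews <- function(temperature, heart_rate, resp_rate, sbp, avpu,
                       table = mews_band_table()) {
  .check_vitals(temperature, heart_rate, resp_rate, sbp, spo2 = NA)
  avpu <- as.character(avpu)
  bad <- !is.na(avpu) & !(avpu %in% c("A", "V", "P", "U"))
  if (any(bad)) stop("avpu must be one of A, V, P, U", call. = FALSE)
  component_points(table, "temperature", temperature) +
    component_points(table, "heart_rate", heart_rate) +
    component_points(table, "resp_rate", resp_rate) +
    component_points(table, "sbp", sbp) +
    component_points(table, "avpu", avpu)
}

#' quick Sequential Organ Failure Assessment (qSOFA)
#'
#' One point each for respiratory rate >= 22, SBP <= 100 and GCS < 15.
#'
#' @inheritParams score_mews
#' @param gcs Glasgow Coma Scale total in 3-15.
#' @param table score band table; defaults to [qsofa_band_table()].
#' @return integer qSOFA total in 0-3; `NA` where any component is missing.
#' @export
score_qsofa <- function(resp_rate, sbp, gcs, table = qsofa_band_table()) {
  .check_range(resp_rate, 0, 90, "resp_rate")
  .check_range(sbp, 0, 300, "sbp")
  .check_range(gcs, 3, 15, "gcs", integer = TRUE)
  component_points(table, "resp_rate", resp_rate) +
    component_points(table, "sbp", sbp) +
    component_points(table, "gcs", gcs)
}

#' Universal Vital Assessment (UVA) score
#'
#' Sums the component points of [uva_band_table()]: temperature < 36 (2),
#' heart rate >= 120 (1), respiratory rate >= 30 (1), SBP < 90 (1), oxygen
#' saturation < 92 (2), GCS < 15 (4) and HIV-positive status (2). An unknown
#' HIV status scores 0, identically to a negative status.
#'
#' @inheritParams score_mews
#' @param spo2 peripheral oxygen saturation, percent.
#' @param gcs Glasgow Coma Scale total in 3-15.
#' @param hiv HIV status: `"positive"`, `"negative"` or `"unknown"`.
#' @param table score band table; defaults to [uva_band_table()].
#' @return integer UVA total (0-13 under the default table); `NA` where any
#'   vital-sign component is missing.
#' @export
score_uva <- function(temperature, heart_rate, resp_rate, sbp, spo2, gcs, hiv,
                      table = uva_band_table()) {
  .check_vitals(temperature, heart_rate, resp_rate, sbp, spo2)
  .check_range(gcs, 3, 15, "gcs", integer = TRUE)
  hiv <- as.character(hiv)
  bad <- !is.na(hiv) & !(hiv %in% c("positive", "negative", "unknown"))
  if (any(bad)) stop("hiv must be positive, negative or unknown", call. = FALSE)
  component_points(table, "temperature", temperature) +
    component_points(table, "heart_rate", heart_rate) +
    component_points(table, "resp_rate", resp_rate) +
    component_points(table, "sbp", sbp) +
    component_points(table, "spo2", spo2) +
    component_points(table, "gcs", gcs) +
    component_points(table, "hiv", hiv)
}

#' Add HIV status to an existing severity score
#'
#' Exploratory score variant: adds a fixed number of points to the base score
#' for HIV-positive participants, leaving negative/unknown unchanged. The
#' default of 2 points mirrors the weight HIV carries in the UVA score.
#'
#' @param base_score non-negative integer score (e.g. MEWS or qSOFA).
#' @param hiv HIV status: `"positive"`, `"negative"` or `"unknown"`.
#' @param hiv_points points added when positive (default 2).
#' @return adjusted integer score.
#' @export
score_plus_hiv <- function(base_score, hiv, hiv_points = 2L) {
  if (any(!is.na(base_score) & base_score < 0)) {
    stop("base_score must be non-negative", call. = FALSE)
  }
  if (length(hiv_points) != 1 || is.na(hiv_points) || hiv_points < 0) {
    stop("hiv_points must be a single non-negative integer", call. = FALSE)
  }
  hiv <- as.character(hiv)
  bad <- !is.na(hiv) & !(hiv %in% c("positive", "negative", "unknown"))
  if (any(bad)) stop("hiv must be positive, negative or unknown", call. = FALSE)
  out <- base_score + ifelse(hiv == "positive", as.integer(hiv_points), 0L)
  out[is.na(base_score) | is.na(hiv)] <- NA_integer_
  as.integer(out)
}

#' Compute all three severity scores for a cohort table
#'
#' Appends `gcs`, `avpu`, `mews`, `qsofa` and `uva` columns (and optionally
#' `mews_hiv`, `qsofa_hiv`) to a cohort table in the canonical schema (see
#' [cohort_schema()]). A score is `NA` for any participant missing one of its
#' components.
#'
#' @param cohort data frame in the canonical cohort schema.
#' @param plus_hiv also compute the exploratory `+HIV` variants of MEWS and
#'   qSOFA.
#' @param hiv_points weight for the `+HIV` variants (default 2).
#' @return the cohort with score columns appended.
#' @export
compute_scores <- function(cohort, plus_hiv = FALSE, hiv_points = 2L) {
  check_cohort_schema(cohort)
  cohort$gcs <- modified_gcs(cohort$gcs_eye, cohort$gcs_verbal,
                             cohort$motor_category)
  cohort$avpu <- gcs_to_avpu(cohort$gcs)
  cohort$mews <- score_mews(cohort$temperature_c, cohort$heart_rate,
                            cohort$resp_rate, cohort$sbp_mmhg, cohort$avpu)
  cohort$qsofa <- score_qsofa(cohort$resp_rate, cohort$sbp_mmhg, cohort$gcs)
  cohort$uva <- score_uva(cohort$temperature_c, cohort$heart_rate,
                          cohort$resp_rate, cohort$sbp_mmhg, cohort$spo2_pct,
                          cohort$gcs, cohort$hiv_status)
  if (plus_hiv) {
    cohort$mews_hiv <- score_plus_hiv(cohort$mews, cohort$hiv_status, hiv_points)
    cohort$qsofa_hiv <- score_plus_hiv(cohort$qsofa, cohort$hiv_status, hiv_points)
  }
  cohort
}
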
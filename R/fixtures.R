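# Published summary tables from the FIEBRE multicentre febrile-cohort
# severity-score validation (four sites: Lao PDR, Malawi, Mozambique,
# Zimbabwe; 2797 complete-case participants, 185 deaths by follow-up).
# These printed tables are sufficient statistics for the headline AUC
# results and ship with the package so the ROC machinery can be exercised
# and checked without the participant-level dataset.

#' Published qSOFA score-by-outcome counts
#'
#' The complete-case qSOFA distribution stratified by vital status at
#' follow-up: 1387/1047/176/2 survivors and 49/79/50/7 deaths at scores
#' 0-3. The tie-corrected AUC of these counts is 0.68 with DeLong 95% CI
#' (0.64, 0.72).
#'
#' @return a [score_counts()] object.
#' @seealso [fiebre_ladder()] for the published Se/Sp ladders.
#' @export
fiebre_qsofa_counts <- function() {
  score_counts(0:3, alive = c(1387, 1047, 176, 2), dead = c(49, 79, 50, 7))
}

#' Published sensitivity/specificity ladders for MEWS, qSOFA and UVA
#'
#' Operating characteristics (percent, 2 dp) of each score at every integer
#' threshold, positivity being score >= threshold, among 185 deaths and 2612
#' survivors. Inverting a ladder with
#' [reconstruct_counts_from_ladder()] recovers per-level outcome counts and
#' hence the published AUCs (MEWS 0.67, qSOFA 0.68, UVA 0.82).
#'
#' @param score `"mews"`, `"qsofa"` or `"uva"`.
#' @return data frame with columns `threshold`, `specificity`,
#'   `sensitivity`, `npv`, `ppv` (NA where the published cell is blank).
#' @export
fiebre_ladder <- function(score = c("mews", "qsofa", "uva")) {
  score <- match.arg(score)
  switch(score,
    mews = data.frame(
      threshold = 0:11,
      specificity = c(0, 22.32, 42.84, 63.09, 77.34, 87.17, 94.87, 98.47,
                      99.73, 99.96, 100, 100),
      sensitivity = c(100, 91.35, 77.30, 63.24, 45.41, 29.19, 20.00, 8.11,
                      4.86, 1.62, 1.08, 0),
      npv = c(NA, 97.33, 96.38, 96.04, 95.24, 94.56, 94.36, 93.80, 93.67,
              93.48, 93.45, 93.39),
      ppv = c(6.61, 7.69, 8.74, 10.82, 12.43, 13.88, 21.64, 27.27, 56.25,
              75.00, 100.00, NA)),
    qsofa = data.frame(
      threshold = 0:4,
      specificity = c(0, 53.10, 93.19, 99.92, 100),
      sensitivity = c(100, 73.51, 30.81, 3.78, 0),
      npv = c(NA, 96.59, 95.00, 93.62, 93.39),
      ppv = c(6.61, 9.99, 24.26, 77.78, NA)),
    uva = data.frame(
      threshold = 0:11,
      specificity = c(0, 56.97, 72.47, 89.78, 95.21, 97.78, 98.85, 99.58,
                      99.85, 99.92, 100, 100),
      sensitivity = c(100, 87.57, 81.62, 55.14, 36.22, 22.70, 13.51, 4.86,
                      2.16, 1.08, 0.54, 0),
      npv = c(NA, 98.48, 98.24, 96.58, 95.47, 94.70, 94.16, 93.66, 93.51,
              93.45, 93.42, 93.39),
      ppv = c(6.61, 12.60, 17.36, 27.64, 34.90, 42.00, 45.45, 45.00, 50.00,
              50.00, 100.00, NA)))
}

#' Published class totals for the complete-case analysis
#'
#' @return named list with `n_dead` (185), `n_alive` (2612), `n_total`
#'   (2797).
#' @export
fiebre_totals <- function() {
  list(n_dead = 185, n_alive = 2612, n_total = 2797)
}

#' Published HIV status by outcome counts
#'
#' Survivors/deaths among HIV-positive (573/112) and HIV-negative (2039/73)
#' participants, from the outcome-stratified descriptive table, together
#' with that table's printed row totals (675 and 2104). Note the published
#' table is internally inconsistent: the cells sum to 685 and 2112, not the
#' printed totals (which also disagree with the overall descriptive table).
#' The headline "17%" mortality among participants living with HIV is
#' 112/675 = 16.6% on the printed total; both denominators are exposed so
#' either convention can be reproduced.
#'
#' @return data frame with rows `positive`/`negative` and columns `alive`,
#'   `dead`, `printed_total`.
#' @export
fiebre_hiv_counts <- function() {
  data.frame(row.names = c("positive", "negative"),
             alive = c(573, 2039), dead = c(112, 73),
             printed_total = c(675, 2104))
}

#' Reconstructed score counts for any of the three scores
#'
#' qSOFA counts are taken directly from the published score-by-outcome
#' table; MEWS and UVA counts are reconstructed by inverting the published
#' Se/Sp ladders against the class totals.
#'
#' @param score `"mews"`, `"qsofa"` or `"uva"`.
#' @return a [score_counts()] object.
#' @export
fiebre_score_counts <- function(score = c("mews", "qsofa", "uva")) {
  score <- match.arg(score)
  if (score == "qsofa") return(fiebre_qsofa_counts())
  lad <- fiebre_ladder(score)
  tot <- fiebre_totals()
  reconstruct_counts_from_ladder(lad$threshold, lad$sensitivity,
                                 lad$specificity, tot$n_dead, tot$n_alive)
}

#' Write the packaged reference tables as CSV files
#'
#' Emits `qsofa_counts.csv` (level/alive/dead) and one
#' `<score>_ladder.csv` per score into `dir`.
#'
#' @param dir destination directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_fixture_csvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "qsofa_counts.csv")
  write_score_counts(fiebre_qsofa_counts(), f)
  files <- c(files, f)
  for (s in c("mews", "qsofa", "uva")) {
    f <- file.path(dir, paste0(s, "_ladder.csv"))
    utils::write.csv(fiebre_ladder(s), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
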
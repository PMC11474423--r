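# Synthetic febrile-cohort generator. Emulates the statistical structure of
# a four-site multicentre febrile-adult cohort: site-specific HIV prevalence
# (<1%-51%), inpatient fractions (23%-45%) and mortality (2%-12%); vital
# signs centred on the published medians/IQRs; ~7% overall 28-day mortality
# concentrated in high-severity strata; 12% loss to follow-up and
# component-wise missingness.
#
# Construction: each participant carries a single latent severity factor
# z ~ N(0, 1). Vitals load on z (oxygen saturation and consciousness most
# strongly, mirroring the published finding that the UVA components carry
# more mortality signal than the MEWS/qSOFA components), admission
# (inpatient status) is a logistic function of z, and death is a logistic
# function of z, HIV, age and inpatient status. Site intercepts for
# admission and death are calibrated by numerical integration so the
# marginal fractions hit the published per-site targets exactly in
# expectation.

#' Canonical cohort column names
#'
#' @return character vector of the canonical per-participant columns.
#' @export
cohort_schema <- function() {
  c("participant_id", "site", "age_years", "sex", "patient_group",
    "temperature_c", "heart_rate", "resp_rate", "sbp_mmhg", "spo2_pct",
    "gcs_eye", "gcs_verbal", "motor_category", "hiv_status", "outcome",
    "time_to_death_days")
}

#' Check a data frame against the canonical cohort schema
#'
#' @param cohort data frame.
#' @return `TRUE` invisibly, or an error listing every missing column.
#' @export
check_cohort_schema <- function(cohort) {
  missing <- setdiff(cohort_schema(), names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Default site profiles
#'
#' Enrolment weight, HIV prevalence, inpatient fraction, target mortality,
#' female fraction, age-band distribution and respiratory-rate location per
#' site, pinned to the published descriptive tables of the four-site study
#' (Lao PDR, Malawi, Mozambique, Zimbabwe).
#'
#' @return data frame, one row per site.
#' @export
site_profiles <- function() {
  data.frame(
    site = c("lao_pdr", "malawi", "mozambique", "zimbabwe"),
    weight = c(412, 727, 811, 847),
    hiv_prevalence = c(0.002, 102 / 727, 413 / 811, 169 / 847),
    inpatient_fraction = c(178 / 412, 169 / 727, 352 / 811, 359 / 847),
    target_mortality = c(23 / 412, 16 / 727, 95 / 811, 51 / 847),
    female_fraction = c(0.57, 0.63, 0.66, 0.54),
    rr_log_median = log(c(22, 22, 19.5, 19.5)),
    rr_log_sd = c(0.10, 0.14, 0.08, 0.08),
    stringsAsFactors = FALSE
  )
}

# Age-band sampling probabilities per site (bands 15-<25 ... 65+), from the
# published age-group percentages.
.age_probs <- function() {
  rbind(
    lao_pdr    = c(0.22, 0.24, 0.16, 0.14, 0.12, 0.12),
    malawi     = c(0.35, 0.30, 0.21, 0.08, 0.04, 0.02),
    mozambique = c(0.23, 0.27, 0.23, 0.11, 0.09, 0.07),
    zimbabwe   = c(0.30, 0.29, 0.21, 0.11, 0.05, 0.04)
  )
}

.age_band_bounds <- cbind(lo = c(15, 25, 35, 45, 55, 65),
                          hi = c(25, 35, 45, 55, 65, 85))

#' Simulation configuration for the synthetic cohort
#'
#' Bundles every generator parameter: sample size, site profiles, the
#' latent-severity loadings of each vital sign, the mortality-model
#' coefficients, loss-to-follow-up and component missingness rates, and the
#' mandatory seed. Site-level intercepts for admission and mortality are
#' calibrated at construction (by numerical integration over the latent
#' severity and covariate distributions) so the expected marginal fractions
#' equal the site profiles' targets.
#'
#' @param n number of participants (default 2797, the published
#'   complete-case size).
#' @param seed integer RNG seed; mandatory for any stochastic call.
#' @param sites site profile data frame (default [site_profiles()]).
#' @param coef_severity log-odds of death per unit latent severity.
#' @param coef_hiv log-odds of death for HIV-positive participants
#'   (exp(1.6) ~ 5, the published adjusted estimate).
#' @param coef_age log-odds of death per decade of age above 32.
#' @param coef_inpatient additional log-odds of death for inpatients.
#' @param inpatient_severity log-odds of admission per unit latent severity.
#' @param gcs_intercept,gcs_slope logistic model for altered consciousness
#'   (GCS < 15) as a function of latent severity.
#' @param ltfu_rate loss-to-follow-up (missing outcome) rate, default 0.12.
#' @param component_missing per-component missingness rate applied to each
#'   of the seven score components (five vitals, consciousness, HIV),
#'   default 0.036 (so ~22% of followed-up records are component-incomplete
#'   and ~68% of all records survive complete-case filtering).
#' @param ltfu_dead_odds odds multiplier on the loss-to-follow-up rate for
#'   participants who died; 1 (default) is missing-completely-at-random,
#'   larger values give an outcome-dependent mechanism for stressing the
#'   sensitivity analyses.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 2797, seed = NULL, sites = site_profiles(),
                       coef_severity = 1.8, coef_hiv = 1.6, coef_age = 0.30,
                       coef_inpatient = 1.0, inpatient_severity = 1.5,
                       gcs_intercept = -6.6, gcs_slope = 3.5,
                       ltfu_rate = 0.12, component_missing = 0.036,
                       ltfu_dead_odds = 1) {
  if (is.null(seed) || is.na(seed)) {
    stop("sim_config requires an integer seed", call. = FALSE)
  }
  rates <- c(ltfu_rate, component_missing)
  if (any(rates < 0 | rates > 1)) {
    stop("ltfu_rate and component_missing must be in [0, 1]", call. = FALSE)
  }
  if (n < 1) stop("n must be positive", call. = FALSE)
  cfg <- list(n = as.integer(n), seed = as.integer(seed), sites = sites,
              coef_severity = coef_severity, coef_hiv = coef_hiv,
              coef_age = coef_age, coef_inpatient = coef_inpatient,
              inpatient_severity = inpatient_severity,
              gcs_intercept = gcs_intercept, gcs_slope = gcs_slope,
              ltfu_rate = ltfu_rate, component_missing = component_missing,
              ltfu_dead_odds = ltfu_dead_odds)
  cfg$sites$inpatient_intercept <- vapply(seq_len(nrow(sites)), function(i) {
    .calibrate_intercept(function(a, z) stats::plogis(a + inpatient_severity * z),
                         target = sites$inpatient_fraction[i])
  }, numeric(1))
  cfg$sites$mortality_intercept <- vapply(seq_len(nrow(sites)), function(i) {
    .calibrate_mortality_intercept(cfg, i)
  }, numeric(1))
  class(cfg) <- "sim_config"
  cfg
}

# Solve E_z[f(a, z)] = target for the intercept a, z ~ N(0, 1).
.calibrate_intercept <- function(f, target) {
  marginal <- function(a) {
    stats::integrate(function(z) f(a, z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-9)$value - target
  }
  stats::uniroot(marginal, c(-20, 20), tol = 1e-9)$root
}

# Mortality intercept for site i: expectation over latent severity,
# HIV (site prevalence), age band (site distribution, band midpoint) and
# inpatient status (logistic in z).
.calibrate_mortality_intercept <- function(cfg, i) {
  s <- cfg$sites[i, ]
  agep <- .age_probs()[s$site, ]
  age_mid <- rowMeans(.age_band_bounds)
  hivp <- c(1 - s$hiv_prevalence, s$hiv_prevalence)
  f <- function(a, z) {
    p_in <- stats::plogis(s$inpatient_intercept + cfg$inpatient_severity * z)
    p <- 0
    for (h in 0:1) for (g in seq_along(agep)) {
      eta <- a + cfg$coef_severity * z + cfg$coef_hiv * h +
        cfg$coef_age * (age_mid[g] - 32) / 10
      p <- p + hivp[h + 1] * agep[g] *
        (p_in * stats::plogis(eta + cfg$coef_inpatient) +
           (1 - p_in) * stats::plogis(eta))
    }
    p
  }
  .calibrate_intercept(f, s$target_mortality)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration: n =", x$n, ", seed =", x$seed, "\n")
  cat("  mortality coefficients: severity", x$coef_severity, "| HIV",
      x$coef_hiv, "| age/decade", x$coef_age, "| inpatient",
      x$coef_inpatient, "\n")
  cat("  loss to follow-up", x$ltfu_rate, "| per-component missingness",
      x$component_missing, "\n")
  print(x$sites[, c("site", "weight", "hiv_prevalence", "inpatient_fraction",
                    "target_mortality")], row.names = FALSE)
  invisible(x)
}

#' Simulate a synthetic febrile cohort
#'
#' Draws a complete cohort (no missingness; see [apply_missingness()]) in
#' the canonical schema, plus a diagnostic column `latent_severity` (the
#' latent factor, kept so parameter-recovery checks can condition on the
#' truth). Scores are computed downstream with [compute_scores()].
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return data frame in the canonical cohort schema (plus
#'   `latent_severity`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  s <- config$sites
  site_idx <- sample.int(nrow(s), n, replace = TRUE, prob = s$weight)
  site <- s$site[site_idx]
  z <- rnorm(n)

  # demographics
  agep <- .age_probs()
  band <- vapply(site_idx, function(i) {
    sample.int(6, 1, prob = agep[s$site[i], ])
  }, integer(1))
  age <- floor(runif(n, .age_band_bounds[band, "lo"],
                     .age_band_bounds[band, "hi"]))
  sex <- ifelse(runif(n) < s$female_fraction[site_idx], "female", "male")
  hiv <- ifelse(runif(n) < s$hiv_prevalence[site_idx], "positive", "negative")
  inpat <- runif(n) < stats::plogis(s$inpatient_intercept[site_idx] +
                                      config$inpatient_severity * z)

  # vitals conditional on latent severity; enrolment requires fever, so
  # temperature is right-shifted above 37.5 and hypothermia never occurs
  temperature <- pmin(42.9, 37.5 + round_to_resolution(0.72 * rexp(n), 0.1))
  heart_rate <- pmin(220, pmax(30, round(99 * exp(0.055 * z + 0.125 * rnorm(n)))))
  resp_rate <- pmin(80, pmax(6, round(exp(
    s$rr_log_median[site_idx] + 0.045 * z + s$rr_log_sd[site_idx] * rnorm(n)))))
  sbp <- pmin(260, pmax(40, round(117 - 3.5 * z + 14.5 * rnorm(n))))
  spo2 <- pmin(100, pmax(40, round(
    98 - 1.4 * abs(rnorm(n)) - 5.5 * pmax(z - 0.4, 0))))

  # consciousness: altered (GCS < 15) is a logistic function of severity
  altered <- runif(n) < stats::plogis(config$gcs_intercept +
                                        config$gcs_slope * z)
  n_alt <- sum(altered)
  gcs_eye <- rep(4L, n)
  gcs_verbal <- rep(5L, n)
  motor <- rep("spontaneous_or_verbal", n)
  if (n_alt > 0) {
    gcs_eye[altered] <- sample(1:4, n_alt, replace = TRUE,
                               prob = c(0.15, 0.20, 0.30, 0.35))
    gcs_verbal[altered] <- sample(1:5, n_alt, replace = TRUE,
                                  prob = c(0.10, 0.15, 0.20, 0.25, 0.30))
    motor[altered] <- sample(c("spontaneous_or_verbal", "pain_only", "none"),
                             n_alt, replace = TRUE, prob = c(0.55, 0.30, 0.15))
    # "altered" must actually score below 15
    full <- altered & gcs_eye == 4L & gcs_verbal == 5L &
      motor == "spontaneous_or_verbal"
    gcs_verbal[full] <- 4L
  }

  # 28-day mortality
  eta <- s$mortality_intercept[site_idx] + config$coef_severity * z +
    config$coef_hiv * (hiv == "positive") +
    config$coef_age * (age - 32) / 10 +
    config$coef_inpatient * inpat
  dead <- runif(n) < stats::plogis(eta)
  ttd <- rep(NA_real_, n)
  ttd[dead] <- pmin(48, pmax(1, round(rlnorm(sum(dead), log(10), 1.3))))

  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    site = site,
    age_years = age,
    sex = sex,
    patient_group = ifelse(inpat, "inpatient", "outpatient"),
    temperature_c = temperature,
    heart_rate = heart_rate,
    resp_rate = resp_rate,
    sbp_mmhg = sbp,
    spo2_pct = spo2,
    gcs_eye = gcs_eye,
    gcs_verbal = gcs_verbal,
    motor_category = motor,
    hiv_status = hiv,
    outcome = ifelse(dead, "dead", "alive"),
    time_to_death_days = ttd,
    latent_severity = z,
    stringsAsFactors = FALSE
  )
}

#' Apply loss to follow-up and component missingness to a cohort
#'
#' Marks the follow-up outcome `"missing"` at the loss-to-follow-up rate
#' (optionally with higher odds for deaths, `ltfu_dead_odds`) and each of
#' the seven score components (temperature, heart rate, respiratory rate,
#' SBP, SpO2, consciousness, HIV status) `NA` independently at the
#' per-component rate. Component missingness is independent of outcome
#' (missing completely at random) under the defaults. Uses the RNG stream
#' seeded from `config$seed + 1` so a simulate/missingness pair is
#' deterministic.
#'
#' @param cohort cohort data frame in the canonical schema.
#' @param config a [sim_config()] object.
#' @return the cohort with missingness applied; `time_to_death_days` is
#'   blanked where the outcome is missing.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  check_cohort_schema(cohort)
  set.seed(config$seed + 1L)
  n <- nrow(cohort)
  base_rate <- config$ltfu_rate
  if (base_rate > 0 && config$ltfu_dead_odds != 1) {
    odds <- base_rate / (1 - base_rate)
    rate_dead <- (odds * config$ltfu_dead_odds) /
      (1 + odds * config$ltfu_dead_odds)
    rate <- ifelse(cohort$outcome == "dead", rate_dead, base_rate)
  } else {
    rate <- rep(base_rate, n)
  }
  lost <- runif(n) < rate
  cohort$outcome[lost] <- "missing"
  cohort$time_to_death_days[lost] <- NA_real_
  r <- config$component_missing
  if (r > 0) {
    for (col in c("temperature_c", "heart_rate", "resp_rate", "sbp_mmhg",
                  "spo2_pct")) {
      cohort[[col]][runif(n) < r] <- NA
    }
    gone <- runif(n) < r
    cohort$gcs_eye[gone] <- NA
    cohort$gcs_verbal[gone] <- NA
    cohort$motor_category[gone] <- NA
    cohort$hiv_status[runif(n) < r] <- NA
  }
  cohort
}

#' Read or write a cohort CSV in the canonical schema
#'
#' Missing values are written as empty fields.
#'
#' @param path file path.
#' @return [read_cohort_csv()] returns the cohort data frame;
#'   [write_cohort_csv()] returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  check_cohort_schema(d)
  d
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort_schema(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
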
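test_that("modified GCS sums eye, verbal and the three-level motor points", {
  expect_equal(modified_gcs(4, 5, "spontaneous_or_verbal"), 15)
  expect_equal(modified_gcs(1, 1, "none"), 3)
  expect_equal(modified_gcs(2, 2, "pain_only"), 7)
  expect_equal(modified_gcs(c(4, 1), c(5, 1),
                            c("spontaneous_or_verbal", "none")), c(15, 3))
  expect_error(modified_gcs(5, 5, "none"), "eye_response")
  expect_error(modified_gcs(4, 0, "none"), "verbal_response")
  expect_error(modified_gcs(4, 5, "withdraws"), "motor_category")
})

test_that("GCS converts to AVPU by the standard band correspondence", {
  expect_equal(gcs_to_avpu(15), "A")
  expect_equal(gcs_to_avpu(3), "U")
  expect_equal(gcs_to_avpu(modified_gcs(2, 2, "pain_only")), "P")
  expect_equal(gcs_to_avpu(c(15, 14, 9, 8, 4, 3)),
               c("A", "V", "V", "P", "P", "U"))
  expect_error(gcs_to_avpu(2), "gcs")
})

test_that("MEWS reproduces its published component bands", {
  # cohort-median vitals in an alert patient: only the RR band fires
  expect_equal(score_mews(38.0, 99, 20, 117, "A"), 1)
  # every component in its zero band
  expect_equal(score_mews(36.5, 70, 12, 120, "A"), 0)
  # every component maximal: totals 14, above the conventional 0-11 range
  expect_equal(score_mews(34.0, 135, 31, 65, "U"), 14)
  # boundary-gap policy: the more severe band extends to the boundary
  expect_equal(score_mews(36.5, 40, 12, 120, "A"), 2)   # HR 40 scores 2
  expect_equal(score_mews(36.5, 70, 8, 120, "A"), 2)    # RR 8 scores 2
  expect_equal(score_mews(36.5, 70, 12, 70, "A"), 3)    # SBP 70 scores 3
  expect_equal(score_mews(36.5, 70, 12, 200, "A"), 2)   # SBP 200 scores 2
  # temperature bands at 0.1 resolution
  expect_equal(score_mews(38.4, 70, 12, 120, "A"), 0)
  expect_equal(score_mews(38.5, 70, 12, 120, "A"), 2)
  expect_equal(score_mews(34.9, 70, 12, 120, "A"), 2)
})

test_that("qSOFA awards one point per criterion at its exact threshold", {
  expect_equal(score_qsofa(22, 100, 15), 2)
  expect_equal(score_qsofa(21, 101, 15), 0)
  expect_equal(score_qsofa(30, 80, 12), 3)
  expect_true(all(score_qsofa(seq(6, 60, 2), 110, 15) %in% 0:1))
})

test_that("UVA reproduces its published component bands and HIV handling", {
  expect_equal(score_uva(38.0, 99, 20, 117, 97, 15, "negative"), 0)
  expect_equal(score_uva(35.5, 120, 30, 89, 91, 15, "positive"), 9)
  # all components maximal: totals 13, above the conventional 0-12 range
  expect_equal(score_uva(35.5, 120, 30, 89, 91, 14, "positive"), 13)
  # unknown HIV scores identically to negative on a grid of vitals
  grid <- expand.grid(t = c(35.0, 36.5, 38.5), hr = c(80, 125),
                      rr = c(18, 32), sbp = c(85, 110), spo2 = c(88, 96),
                      gcs = c(12, 15))
  expect_equal(
    with(grid, score_uva(t, hr, rr, sbp, spo2, gcs, "unknown")),
    with(grid, score_uva(t, hr, rr, sbp, spo2, gcs, "negative")))
})

test_that("adding HIV points leaves negative/unknown scores unchanged", {
  expect_equal(score_plus_hiv(3, "positive", 2), 5)
  expect_equal(score_plus_hiv(3, "negative", 2), 3)
  expect_equal(score_plus_hiv(0, "unknown", 2), 0)
  expect_error(score_plus_hiv(-1, "positive"), "non-negative")
  expect_error(score_plus_hiv(3, "positive", -2), "non-negative")
})

test_that("band tables are disjoint and cover every measurable value", {
  for (tab in list(mews_band_table(), qsofa_band_table(), uva_band_table())) {
    expect_true(validate_band_table(tab))
  }
  # every integer HR/RR/SBP and every 0.1-degree temperature maps to exactly
  # one MEWS band (validate_band_table checks this on the resolution grid);
  # also confirm end to end that the total never goes missing
  hr <- 0:300
  expect_false(anyNA(score_mews(37, hr, 16, 120, "A")))
  expect_false(anyNA(score_mews(37, 80, 0:90, 120, "A")))
  expect_false(anyNA(score_mews(37, 80, 16, 0:300, "A")))
  expect_false(anyNA(score_mews(seq(25, 45, 0.1), 80, 16, 120, "A")))
})

test_that("worsening any single component never decreases a score", {
  # every base component sits in its zero-point band (MEWS RR zero band is
  # 9-14, so the RR baseline is 12)
  base <- list(t = 37.0, hr = 80, rr = 12, sbp = 120, spo2 = 98, gcs = 15)
  # MEWS: sweep each vital from its zero band toward each extreme
  mews0 <- score_mews(base$t, base$hr, base$rr, base$sbp, "A")
  expect_true(all(diff(score_mews(seq(37, 45, 0.1), base$hr, base$rr, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(seq(37, 25, -0.1), base$hr, base$rr, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, 80:300, base$rr, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, 80:0, base$rr, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, base$hr, 12:90, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, base$hr, 12:0, base$sbp, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, base$hr, base$rr, 120:0, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, base$hr, base$rr, 120:300, "A")) >= 0))
  expect_true(all(diff(score_mews(base$t, base$hr, base$rr, base$sbp,
                                  c("A", "V", "P", "U"))) >= 0))
  # qSOFA
  expect_true(all(diff(score_qsofa(16:90, base$sbp, 15)) >= 0))
  expect_true(all(diff(score_qsofa(base$rr, 120:0, 15)) >= 0))
  expect_true(all(diff(score_qsofa(base$rr, base$sbp, 15:3)) >= 0))
  # UVA
  expect_true(all(diff(score_uva(seq(37, 25, -0.1), base$hr, base$rr, base$sbp,
                                 base$spo2, 15, "negative")) >= 0))
  expect_true(all(diff(score_uva(base$t, 80:300, base$rr, base$sbp,
                                 base$spo2, 15, "negative")) >= 0))
  expect_true(all(diff(score_uva(base$t, base$hr, 16:90, base$sbp,
                                 base$spo2, 15, "negative")) >= 0))
  expect_true(all(diff(score_uva(base$t, base$hr, base$rr, 120:0,
                                 base$spo2, 15, "negative")) >= 0))
  expect_true(all(diff(score_uva(base$t, base$hr, base$rr, base$sbp,
                                 98:0, 15, "negative")) >= 0))
  expect_true(all(diff(score_uva(base$t, base$hr, base$rr, base$sbp,
                                 base$spo2, 15:3, "negative")) >= 0))
})

test_that("score totals stay inside their structural ranges on a random grid", {
  set.seed(7)
  n <- 2000
  t <- round_to_resolution(runif(n, 25, 45), 0.1)
  hr <- sample(0:300, n, TRUE); rr <- sample(0:90, n, TRUE)
  sbp <- sample(0:300, n, TRUE); spo2 <- sample(0:100, n, TRUE)
  gcs <- sample(c(3:15), n, TRUE)
  avpu <- sample(c("A", "V", "P", "U"), n, TRUE)
  hiv <- sample(c("positive", "negative", "unknown"), n, TRUE)
  expect_true(all(score_mews(t, hr, rr, sbp, avpu) %in% 0:14))
  expect_true(all(score_qsofa(rr, sbp, gcs) %in% 0:3))
  expect_true(all(score_uva(t, hr, rr, sbp, spo2, gcs, hiv) %in% 0:13))
})

test_that("band tables round-trip through JSON bit-exactly", {
  for (make in list(mews_band_table, qsofa_band_table, uva_band_table)) {
    tab <- make()
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path), add = TRUE)
    write_band_table(tab, path)
    back <- read_band_table(path)
    expect_equal(back$name, tab$name)
    expect_equal(back$max_points, tab$max_points)
    for (nm in names(tab$components)) {
      a <- tab$components[[nm]]; b <- back$components[[nm]]
      if (a$type == "interval") {
        expect_identical(as.numeric(unlist(a$bands)), as.numeric(unlist(b$bands)))
      } else {
        expect_identical(a$levels, b$levels)
        expect_identical(a$points, b$points)
      }
    }
  }
  # a custom table can rescore: double the UVA HIV weight
  tab <- uva_band_table()
  tab$components$hiv$points <- c(4L, 0L, 0L)
  expect_equal(score_uva(38, 99, 20, 117, 97, 15, "positive", table = tab), 4)
})

test_that("non-grid measurements are rounded half-up before banding", {
  expect_equal(round_to_resolution(38.45, 0.1), 38.5)
  expect_equal(round_to_resolution(110.5, 1), 111)
  # 110.5 rounds up to 111, entering the MEWS 111-129 band
  expect_equal(score_mews(37, 110.5, 12, 120, "A"),
               score_mews(37, 111, 12, 120, "A"))
  expect_equal(score_mews(38.45, 70, 12, 120, "A"), 2)
})
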
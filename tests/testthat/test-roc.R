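test_that("tie-corrected AUC equals brute-force pair enumeration", {
  set.seed(11)
  for (i in 1:25) {
    counts <- random_counts(n_levels = sample(2:8, 1))
    expect_equal(auc_mann_whitney(counts), oracle_auc(counts),
                 tolerance = 1e-12)
  }
  # degenerate shapes
  expect_equal(auc_mann_whitney(score_counts(0:1, alive = c(10, 0),
                                             dead = c(0, 5))), 1.0)
  expect_equal(auc_mann_whitney(score_counts(0, alive = 10, dead = 5)), 0.5)
  expect_error(auc_mann_whitney(score_counts(0:1, alive = c(5, 5),
                                             dead = c(0, 0))),
               "outcome class")
})

test_that("published qSOFA contingency gives AUC 0.68 with DeLong CI (0.64, 0.72)", {
  est <- auc_delong(fiebre_qsofa_counts())
  expect_equal(round(est$auc, 2), 0.68)
  expect_equal(round(est$ci_low, 2), 0.64)
  expect_equal(round(est$ci_high, 2), 0.72)
})

test_that("DeLong variance matches enumeration and pROC on random counts", {
  set.seed(13)
  for (i in 1:15) {
    counts <- random_counts()
    est <- auc_delong(counts)
    expect_equal(est$variance, oracle_delong_variance(counts),
                 tolerance = 1e-12)
  }
  # balanced two-level toy against the enumeration oracle
  toy <- score_counts(0:1, alive = c(5, 5), dead = c(5, 5))
  expect_equal(auc_delong(toy)$variance, oracle_delong_variance(toy),
               tolerance = 1e-12)
  # perfectly separated counts: zero variance, CI pinned at 1
  sep <- score_counts(0:1, alive = c(12, 0), dead = c(0, 6))
  est <- auc_delong(sep)
  expect_equal(est$auc, 1.0)
  expect_equal(est$variance, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  # independent implementation: pROC's DeLong machinery on expanded data
  e <- expand_counts(fiebre_qsofa_counts())
  r <- pROC::roc(response = c(rep(1, length(e$cases)), rep(0, length(e$controls))),
                 predictor = c(e$cases, e$controls), quiet = TRUE,
                 direction = "<")
  expect_equal(auc_delong(fiebre_qsofa_counts())$variance,
               as.numeric(pROC::var(r, method = "delong")), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(auc_delong(fiebre_qsofa_counts())$ci_low, ci[1], tolerance = 1e-9)
})

test_that("paired DeLong test is null on identity, antisymmetric, and matches oracles", {
  set.seed(17)
  n <- 120
  x <- sample(0:6, n, TRUE)
  dead <- runif(n) < plogis(-2 + 0.5 * x)
  while (sum(dead) < 5) { dead <- runif(n) < plogis(-2 + 0.5 * x) }
  y <- pmax(0, x + sample(-1:1, n, TRUE))
  # identity
  t0 <- delong_test(x, x, dead)
  expect_equal(t0$delta, 0)
  expect_equal(t0$z, 0)
  expect_equal(t0$p_value, 1)
  # antisymmetry
  tab <- delong_test(x, y, dead)
  tba <- delong_test(y, x, dead)
  expect_equal(tab$z, -tba$z)
  expect_equal(tab$delta, -tba$delta)
  expect_equal(tab$p_value, tba$p_value)
  # enumeration oracle on a small paired design
  set.seed(19)
  for (i in 1:10) {
    nn <- 20
    a <- sample(0:4, nn, TRUE); b <- sample(0:4, nn, TRUE)
    d <- c(rep(TRUE, 6), rep(FALSE, 14))
    t <- delong_test(a, b, d)
    expect_equal(t$z, oracle_delong_z(a, b, d), tolerance = 1e-10)
  }
  # independent implementation: pROC paired roc.test
  set.seed(23)
  nn <- 200
  a <- sample(0:8, nn, TRUE)
  d <- runif(nn) < plogis(-2.5 + 0.4 * a)
  b <- pmax(0, a + sample(-2:2, nn, TRUE))
  ours <- delong_test(a, b, d)
  ra <- pROC::roc(d, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(d, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("threshold metrics reproduce the published qSOFA operating row", {
  q <- fiebre_qsofa_counts()
  at2 <- threshold_metrics(q, 2)
  expect_equal(round(at2$sensitivity, 2), 30.81)
  expect_equal(round(at2$specificity, 2), 93.19)
  expect_equal(round(at2$ppv, 2), 24.26)
  expect_equal(round(at2$npv, 2), 95.00)
  at0 <- threshold_metrics(q, 0)
  expect_equal(at0$sensitivity, 100)
  expect_equal(at0$specificity, 0)
  expect_false(at0$npv_defined)
  above <- threshold_metrics(q, 10)
  expect_equal(above$sensitivity, 0)
  expect_equal(above$specificity, 100)
  expect_false(above$ppv_defined)
  # monotonicity along the full ladder
  lad <- threshold_table(q)
  expect_true(all(diff(lad$sensitivity) <= 0))
  expect_true(all(diff(lad$specificity) >= 0))
})

test_that("ROC points pass through the corners and integrate to the AUC", {
  set.seed(29)
  for (i in 1:10) {
    counts <- random_counts()
    pts <- roc_points(counts)
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_equal(trapezoid_auc(pts), auc_mann_whitney(counts),
                 tolerance = 1e-12)
  }
  q <- fiebre_qsofa_counts()
  expect_equal(nrow(roc_points(q)), 5)
  expect_equal(trapezoid_auc(roc_points(q)), auc_mann_whitney(q),
               tolerance = 1e-12)
  one <- score_counts(0, alive = 10, dead = 4)
  expect_equal(trapezoid_auc(roc_points(one)), 0.5)
  sep <- score_counts(0:1, alive = c(10, 0), dead = c(0, 4))
  pts <- roc_points(sep)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
})

test_that("ladder inversion recovers exact counts and inverts threshold_table", {
  tot <- fiebre_totals()
  uva <- fiebre_ladder("uva")
  rec <- reconstruct_counts_from_ladder(uva$threshold, uva$sensitivity,
                                        uva$specificity, tot$n_dead,
                                        tot$n_alive)
  expect_equal(sum(rec$dead), tot$n_dead)
  expect_equal(sum(rec$alive), tot$n_alive)
  expect_equal(rec$dead, c(23, 11, 49, 35, 25, 17, 16, 5, 2, 1, 1))
  mews <- fiebre_ladder("mews")
  recm <- reconstruct_counts_from_ladder(mews$threshold, mews$sensitivity,
                                         mews$specificity, tot$n_dead,
                                         tot$n_alive)
  expect_equal(recm$alive[1], 583)
  # trivial ladder: all mass at one level per class
  tri <- reconstruct_counts_from_ladder(0:1, c(100, 0), c(0, 100), 7, 9)
  expect_equal(tri$dead, 7)
  expect_equal(tri$alive, 9)
  # reconstruct(threshold_table(counts)) is the identity at full precision
  set.seed(31)
  for (i in 1:10) {
    counts <- random_counts()
    lad <- threshold_table(counts)
    back <- reconstruct_counts_from_ladder(lad$threshold, lad$sensitivity,
                                           lad$specificity,
                                           sum(counts$dead), sum(counts$alive))
    expect_equal(back$dead, counts$dead)
    expect_equal(back$alive, counts$alive)
  }
  expect_error(reconstruct_counts_from_ladder(0:1, c(50, 100), c(0, 100), 5, 5),
               "non-increasing")
})

test_that("score counts validate, tabulate and round-trip CSV", {
  expect_error(score_counts(c(0, 0), c(1, 1), c(1, 1)), "strictly increasing")
  expect_error(score_counts(0:1, c(-1, 1), c(1, 1)), "non-negative")
  sc <- count_scores(c(0, 0, 1, 2, 2, 2), c("alive", "dead", "alive",
                                            "dead", "dead", "alive"))
  expect_equal(sc$levels, c(0, 1, 2))
  expect_equal(sc$alive, c(1, 1, 1))
  expect_equal(sc$dead, c(1, 0, 2))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_score_counts(sc, path)
  back <- read_score_counts(path)
  expect_equal(back$levels, sc$levels)
  expect_equal(back$alive, sc$alive)
  expect_equal(back$dead, sc$dead)
})
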
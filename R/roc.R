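# ROC machinery for ordinal severity scores: tie-corrected Mann-Whitney AUC,
# DeLong variance and confidence intervals, the paired DeLong AUC-difference
# test, operating-characteristic threshold tables, and reconstruction of
# score counts from a published sensitivity/specificity ladder.
#
# Everything works from grouped per-level counts (score_counts), which are
# the sufficient statistic: with m deaths and n survivors the Mann-Whitney
# kernel psi(case, control) = 1 if case > control, 1/2 if tied, 0 otherwise
# gives AUC = sum_{pairs} psi / (m n), and the DeLong structural components
# are the per-subject means of psi over the opposite class.

# Per-level structural components. For a case at level k,
# V10(k) = (#controls below k + #controls at k / 2) / n; for a control at k,
# V01(k) = (#cases above k + #cases at k / 2) / m.
.structural_components <- function(counts) {
  alive <- counts$alive
  dead <- counts$dead
  m <- sum(dead)
  n <- sum(alive)
  alive_below <- cumsum(c(0, alive))[seq_along(alive)]
  dead_above <- m - cumsum(dead)
  v10_level <- (alive_below + alive / 2) / n
  v01_level <- (dead_above + dead / 2) / m
  list(m = m, n = n,
       v10 = rep(v10_level, dead),   # one entry per case
       v01 = rep(v01_level, alive))  # one entry per control
}

#' Tie-corrected Mann-Whitney AUC from score counts
#'
#' The probability that a randomly chosen case (death) has a strictly higher
#' score than a randomly chosen control (survivor), counting ties as 1/2.
#' Identical to the trapezoidal area under the empirical ROC step curve with
#' tied levels traversed along diagonals.
#'
#' @param counts a [score_counts()] object (or anything [count_scores()]
#'   accepts via `score`/`outcome` below).
#' @return the AUC as a single number in \[0, 1\].
#' @export
auc_mann_whitney <- function(counts) {
  .check_two_classes(counts)
  sc <- .structural_components(counts)
  # mean over cases of P(case > control) is the AUC
  mean(sc$v10)
}

.check_two_classes <- function(counts, min_per_class = 1) {
  stopifnot(inherits(counts, "score_counts"))
  if (sum(counts$dead) < min_per_class || sum(counts$alive) < min_per_class) {
    stop("AUC undefined: need at least ", min_per_class,
         " subject(s) in each outcome class", call. = FALSE)
  }
  invisible(counts)
}

#' AUC with DeLong variance and Wald confidence interval
#'
#' Computes the tie-corrected AUC together with its DeLong variance
#' S10/m + S01/n, where S10 and S01 are the sample variances of the
#' per-subject structural components over the m cases and n controls, and a
#' Wald confidence interval clipped to \[0, 1\].
#'
#' @param counts a [score_counts()] object.
#' @param conf.level confidence level for the interval (default 0.95).
#' @return an object of class `auc_estimate` with fields `auc`, `variance`,
#'   `ci_low`, `ci_high`, `conf.level`, `m` (cases), `n` (controls).
#' @examples
#' qsofa <- score_counts(0:3, alive = c(1387, 1047, 176, 2),
#'                       dead = c(49, 79, 50, 7))
#' auc_delong(qsofa)  # 0.68 (0.64, 0.72)
#' @export
auc_delong <- function(counts, conf.level = 0.95) {
  .check_two_classes(counts, min_per_class = 2)
  sc <- .structural_components(counts)
  auc <- mean(sc$v10)
  v <- stats::var(sc$v10) / sc$m + stats::var(sc$v01) / sc$n
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(v)
  structure(list(auc = auc, variance = v,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 conf.level = conf.level, m = sc$m, n = sc$n),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (%.0f%% CI %.*f-%.*f), %d cases / %d controls\n",
              digits, x$auc, 100 * x$conf.level, digits, x$ci_low,
              digits, x$ci_high, x$m, x$n))
  invisible(x)
}

#' Paired DeLong test comparing two AUCs on the same subjects
#'
#' Tests the difference between the AUCs of two scores measured on the same
#' subjects, using the DeLong structural-component covariance:
#' z = (AUC_a - AUC_b) / sqrt(Var(A) + Var(B) - 2 Cov(A, B)), with a
#' two-sided p-value from the standard normal. When the two scores induce
#' identical orderings the statistic is 0 and p = 1.
#'
#' @param scores_a,scores_b per-subject score values for the two scores
#'   (equal length, same subjects).
#' @param outcome per-subject outcome (`"alive"`/`"dead"`, 0/1 or logical).
#' @param conf.level confidence level for the interval on the AUC difference.
#' @return an object of class `delong_test` with fields `auc_a`, `auc_b`,
#'   `delta`, `variance_delta`, `z`, `p_value`, `ci_low`, `ci_high`.
#' @export
delong_test <- function(scores_a, scores_b, outcome, conf.level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcome)) {
    stop("scores_a, scores_b and outcome must have equal length", call. = FALSE)
  }
  dead <- .as_dead(outcome)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(dead)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; dead <- dead[keep]
  m <- sum(dead); n <- sum(!dead)
  if (m < 2 || n < 2) {
    stop("paired DeLong test needs at least 2 subjects per outcome class",
         call. = FALSE)
  }
  comp <- function(score) {
    x <- score[dead]    # cases
    y <- score[!dead]   # controls
    # per-case and per-control means of the Mann-Whitney kernel
    v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  var_delta <- (stats::var(a$v10) + stats::var(b$v10) -
                  2 * stats::cov(a$v10, b$v10)) / m +
               (stats::var(a$v01) + stats::var(b$v01) -
                  2 * stats::cov(a$v01, b$v01)) / n
  delta <- a$auc - b$auc
  if (var_delta <= .Machine$double.eps) {
    z <- if (abs(delta) < .Machine$double.eps^0.5) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
  }
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  hw <- if (var_delta > 0) zq * sqrt(var_delta) else 0
  structure(list(auc_a = a$auc, auc_b = b$auc, delta = delta,
                 variance_delta = max(var_delta, 0), z = z, p_value = p,
                 ci_low = delta - hw, ci_high = delta + hw,
                 conf.level = conf.level, m = m, n = n),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, digits = 3, ...) {
  cat(sprintf("Paired DeLong test: AUC %.*f vs %.*f, delta %+.*f, z = %.2f, p = %s\n",
              digits, x$auc_a, digits, x$auc_b, digits, x$delta, x$z,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Operating characteristics at one score threshold
#'
#' Positivity is score >= threshold. Sensitivity is the percentage of deaths
#' at or above the threshold; specificity the percentage of survivors below
#' it; PPV the percentage of deaths among test-positives and NPV the
#' percentage of survivors among test-negatives. PPV (NPV) is `NA` with
#' `ppv_defined` (`npv_defined`) `FALSE` when no subject is test-positive
#' (test-negative), mirroring the blank cells of published threshold tables.
#'
#' @param counts a [score_counts()] object.
#' @param threshold score value defining positivity (score >= threshold).
#' @return a one-row data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percentages at full precision),
#'   `ppv_defined`, `npv_defined`.
#' @export
threshold_metrics <- function(counts, threshold) {
  .check_two_classes(counts)
  pos <- counts$levels >= threshold
  tp <- sum(counts$dead[pos]);  fn <- sum(counts$dead[!pos])
  fp <- sum(counts$alive[pos]); tn <- sum(counts$alive[!pos])
  ppv_def <- (tp + fp) > 0
  npv_def <- (tn + fn) > 0
  data.frame(
    threshold = threshold,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = if (ppv_def) 100 * tp / (tp + fp) else NA_real_,
    npv = if (npv_def) 100 * tn / (tn + fn) else NA_real_,
    ppv_defined = ppv_def, npv_defined = npv_def)
}

#' Full operating-characteristic ladder over all thresholds
#'
#' @param counts a [score_counts()] object.
#' @param thresholds score thresholds; defaults to every observed level plus
#'   one above the maximum (where sensitivity is 0 and specificity 100).
#' @return data frame of [threshold_metrics()] rows, threshold ascending.
#' @export
threshold_table <- function(counts, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- c(counts$levels, max(counts$levels) + 1)
  }
  out <- do.call(rbind, lapply(sort(thresholds), threshold_metrics, counts = counts))
  rownames(out) <- NULL
  out
}

#' ROC curve coordinates for an ordinal score
#'
#' One point per threshold, ordered from (0, 0) (threshold above the maximum
#' score) to (1, 1) (threshold at or below the minimum). The trapezoidal area
#' under these points equals [auc_mann_whitney()] exactly.
#'
#' @param counts a [score_counts()] object.
#' @return data frame with columns `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), both proportions.
#' @export
roc_points <- function(counts) {
  .check_two_classes(counts)
  m <- sum(counts$dead); n <- sum(counts$alive)
  # one point per threshold, descending threshold = ascending fpr/tpr;
  # threshold above the max gives (0, 0), at the min everyone is positive
  dead_ge <- rev(cumsum(rev(counts$dead)))
  alive_ge <- rev(cumsum(rev(counts$alive)))
  pts <- data.frame(fpr = c(0, rev(alive_ge) / n),
                    tpr = c(0, rev(dead_ge) / m))
  rownames(pts) <- NULL
  pts
}

#' Trapezoidal area under ROC points
#'
#' @param pts data frame from [roc_points()].
#' @return the trapezoidal area, equal to the tie-corrected AUC.
#' @export
trapezoid_auc <- function(pts) {
  x <- pts$fpr; y <- pts$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Reconstruct score counts from a published Se/Sp ladder
#'
#' Inverts a printed operating-characteristic table: for each threshold t the
#' number of deaths at or above t is `n_dead * Se(t) / 100` and the number of
#' survivors below t is `n_alive * Sp(t) / 100`, rounded half-up to the
#' nearest integer; per-level counts are the differences of consecutive
#' cumulative totals. Counts sum exactly to `n_dead` and `n_alive` provided
#' the ladder starts at a threshold with Se 100 / Sp 0 and ends above the
#' maximum level (Se 0 / Sp 100).
#'
#' @param thresholds ascending score thresholds, typically `0:K`.
#' @param sensitivity percentage of deaths at or above each threshold
#'   (non-increasing).
#' @param specificity percentage of survivors below each threshold
#'   (non-decreasing).
#' @param n_dead,n_alive class totals.
#' @return a [score_counts()] object on levels `thresholds[-length]`.
#' @export
reconstruct_counts_from_ladder <- function(thresholds, sensitivity,
                                           specificity, n_dead, n_alive) {
  k <- length(thresholds)
  if (length(sensitivity) != k || length(specificity) != k) {
    stop("thresholds, sensitivity and specificity must have equal length",
         call. = FALSE)
  }
  if (is.unsorted(rev(sensitivity))) {
    stop("sensitivity must be non-increasing in threshold", call. = FALSE)
  }
  if (is.unsorted(specificity)) {
    stop("specificity must be non-decreasing in threshold", call. = FALSE)
  }
  dead_ge <- floor(n_dead * sensitivity / 100 + 0.5)
  alive_lt <- floor(n_alive * specificity / 100 + 0.5)
  dead <- dead_ge[-k] - dead_ge[-1]
  alive <- alive_lt[-1] - alive_lt[-k]
  if (any(dead < 0) || any(alive < 0)) {
    stop("negative per-level count after rounding; ladder inconsistent with totals",
         call. = FALSE)
  }
  score_counts(thresholds[-k], alive = alive, dead = dead)
}
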
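# End-to-end validation pipeline: complete-case filtering, score
# computation, per-score AUCs with DeLong CIs, pairwise DeLong tests,
# threshold ladders, subgroup and missing-outcome sensitivity analyses, and
# structured report rendering.

.component_cols <- c("temperature_c", "heart_rate", "resp_rate", "sbp_mmhg",
                     "spo2_pct", "gcs_eye", "gcs_verbal", "motor_category",
                     "hiv_status")

#' Complete-case filter with flow accounting
#'
#' Retains participants with every score component, HIV status and a
#' non-missing alive/dead outcome. Removal is accounted in enrolment-flow
#' order: loss to follow-up (missing outcome) first, then incomplete score
#' components among those followed up.
#'
#' @param cohort cohort data frame in the canonical schema.
#' @return list with `cohort` (the filtered rows) and `flow` (named counts:
#'   `enrolled`, `lost_to_follow_up`, `incomplete_components`, `analysed`).
#' @export
complete_case_filter <- function(cohort) {
  check_cohort_schema(cohort)
  n0 <- nrow(cohort)
  lost <- is.na(cohort$outcome) | cohort$outcome == "missing"
  followed <- cohort[!lost, , drop = FALSE]
  incomplete <- !stats::complete.cases(followed[, .component_cols])
  analysed <- followed[!incomplete, , drop = FALSE]
  flow <- c(enrolled = n0,
            lost_to_follow_up = sum(lost),
            incomplete_components = sum(incomplete),
            analysed = nrow(analysed))
  message("complete-case filter: ", n0, " enrolled; ", sum(lost),
          " lost to follow-up; ", sum(incomplete),
          " with missing score components; ", nrow(analysed), " analysed")
  list(cohort = analysed, flow = flow)
}

#' Impute missing follow-up outcomes for sensitivity analysis
#'
#' Replaces `"missing"` outcomes by the stated value (`"alive"` or
#' `"dead"`). Records with incomplete score components remain incomplete
#' and are still excluded downstream.
#'
#' @param cohort cohort data frame in the canonical schema.
#' @param mode `"alive"` or `"dead"`.
#' @return the cohort with imputed outcomes.
#' @export
sensitivity_impute_outcome <- function(cohort, mode = c("alive", "dead")) {
  mode <- match.arg(mode)
  check_cohort_schema(cohort)
  missing <- is.na(cohort$outcome) | cohort$outcome == "missing"
  cohort$outcome[missing] <- mode
  cohort
}

.auc_row <- function(score, outcome, conf.level = 0.95) {
  counts <- count_scores(score, outcome)
  if (sum(counts$dead) < 2 || sum(counts$alive) < 2) {
    return(list(auc = NA_real_, variance = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, m = sum(counts$dead),
                n = sum(counts$alive),
                reason = "fewer than 2 subjects in an outcome class"))
  }
  est <- auc_delong(counts, conf.level)
  list(auc = est$auc, variance = est$variance, ci_low = est$ci_low,
       ci_high = est$ci_high, m = est$m, n = est$n, reason = NULL)
}

.pairwise_tests <- function(scored, score_cols, conf.level = 0.95) {
  pairs <- utils::combn(score_cols, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    # report higher-AUC score first so deltas read like published tables
    t <- delong_test(scored[[p[1]]], scored[[p[2]]], scored$outcome,
                     conf.level = conf.level)
    if (t$delta < 0) {
      t <- delong_test(scored[[p[2]]], scored[[p[1]]], scored$outcome,
                       conf.level = conf.level)
      p <- rev(p)
    }
    list(score_a = p[1], score_b = p[2], test = t)
  })
  names(out) <- vapply(out, function(x) {
    paste(x$score_a, "vs", x$score_b)
  }, character(1))
  out
}

#' Run the full severity-score validation analysis
#'
#' The package's central entry point. Filters to complete cases, computes
#' MEWS, qSOFA and UVA (plus optional +HIV variants), and assembles: each
#' score's tie-corrected AUC with DeLong confidence interval, all pairwise
#' DeLong comparisons, full threshold ladders
#' (sensitivity/specificity/PPV/NPV), subgroup AUCs (by site and patient
#' group), both missing-outcome sensitivity analyses, and unadjusted plus
#' adjusted odds-ratio tables. Deterministic given the input.
#'
#' @param cohort cohort data frame in the canonical schema (with or without
#'   missingness).
#' @param plus_hiv also analyse the exploratory MEWS+HIV and qSOFA+HIV
#'   variants.
#' @param hiv_points weight for the +HIV variants (default 2).
#' @param subgroups columns to stratify AUCs by (default site and patient
#'   group); a stratum with fewer than two subjects in either outcome class
#'   yields an undefined AUC with a reason, not an error.
#' @param or_tables fit unadjusted/adjusted odds-ratio tables (default
#'   TRUE; disable for speed on large simulation sweeps).
#' @param min_count sparse-level grouping threshold for the models.
#' @param conf.level confidence level throughout.
#' @return an object of class `fevscore_report`.
#' @export
validate_scores <- function(cohort, plus_hiv = FALSE, hiv_points = 2L,
                            subgroups = c("site", "patient_group"),
                            or_tables = TRUE, min_count = 5,
                            conf.level = 0.95) {
  cc <- complete_case_filter(cohort)
  scored <- compute_scores(cc$cohort, plus_hiv = plus_hiv,
                           hiv_points = hiv_points)
  score_cols <- c("mews", "qsofa", "uva")
  if (plus_hiv) score_cols <- c(score_cols, "mews_hiv", "qsofa_hiv")

  aucs <- lapply(score_cols, function(sc) {
    .auc_row(scored[[sc]], scored$outcome, conf.level)
  })
  names(aucs) <- score_cols

  pairwise <- .pairwise_tests(scored, score_cols, conf.level)

  ladders <- lapply(score_cols, function(sc) {
    threshold_table(count_scores(scored[[sc]], scored$outcome))
  })
  names(ladders) <- score_cols

  subgroup_aucs <- list()
  for (g in subgroups) {
    levels_g <- sort(unique(scored[[g]]))
    subgroup_aucs[[g]] <- lapply(stats::setNames(levels_g, levels_g),
      function(lv) {
        sub <- scored[scored[[g]] == lv, , drop = FALSE]
        lapply(stats::setNames(score_cols, score_cols), function(sc) {
          .auc_row(sub[[sc]], sub$outcome, conf.level)
        })
      })
  }

  sensitivity <- lapply(c(alive = "alive", dead = "dead"), function(mode) {
    imputed <- sensitivity_impute_outcome(cohort, mode)
    cc_i <- suppressMessages(complete_case_filter(imputed))
    scored_i <- compute_scores(cc_i$cohort, plus_hiv = plus_hiv,
                               hiv_points = hiv_points)
    list(aucs = stats::setNames(lapply(score_cols, function(sc) {
           .auc_row(scored_i[[sc]], scored_i$outcome, conf.level)
         }), score_cols),
         pairwise = .pairwise_tests(scored_i, score_cols, conf.level),
         n = nrow(scored_i))
  })

  ors <- NULL
  if (or_tables) {
    ors <- lapply(stats::setNames(c("mews", "qsofa", "uva"),
                                  c("mews", "qsofa", "uva")), function(sc) {
      covs <- if (sc == "uva") c("age_group", "sex") else
        c("age_group", "sex", "hiv")
      list(unadjusted = adjusted_model(scored, sc, covariates = character(0),
                                       min_count = min_count,
                                       conf.level = conf.level),
           adjusted = adjusted_model(scored, sc, covariates = covs,
                                     min_count = min_count,
                                     conf.level = conf.level))
    })
  }

  structure(list(flow = cc$flow, scores = score_cols, aucs = aucs,
                 pairwise = pairwise, ladders = ladders,
                 subgroups = subgroup_aucs, sensitivity = sensitivity,
                 or_tables = ors, conf.level = conf.level,
                 scored = scored),
            class = "fevscore_report")
}

#' @export
print.fevscore_report <- function(x, digits = 2, ...) {
  f <- x$flow
  cat("Severity-score validation report\n")
  cat(sprintf("  %d enrolled; %d lost to follow-up; %d incomplete; %d analysed\n",
              f["enrolled"], f["lost_to_follow_up"],
              f["incomplete_components"], f["analysed"]))
  cat("  AUC (", 100 * x$conf.level, "% CI):\n", sep = "")
  for (sc in x$scores) {
    a <- x$aucs[[sc]]
    if (is.na(a$auc)) {
      cat(sprintf("    %-9s undefined (%s)\n", sc, a$reason))
    } else {
      cat(sprintf("    %-9s %.*f (%.*f-%.*f)\n", sc, digits, a$auc,
                  digits, a$ci_low, digits, a$ci_high))
    }
  }
  cat("  Pairwise DeLong tests:\n")
  for (nm in names(x$pairwise)) {
    t <- x$pairwise[[nm]]$test
    cat(sprintf("    %-18s delta %+.*f, p = %s\n", nm, digits, t$delta,
                format.pval(t$p_value, digits = 3)))
  }
  invisible(x)
}

#' @export
summary.fevscore_report <- function(object, ...) {
  auc_df <- do.call(rbind, lapply(object$scores, function(sc) {
    a <- object$aucs[[sc]]
    data.frame(score = sc, auc = a$auc, ci_low = a$ci_low,
               ci_high = a$ci_high, cases = a$m, controls = a$n)
  }))
  pw_df <- do.call(rbind, lapply(object$pairwise, function(p) {
    data.frame(comparison = paste(p$score_a, "vs", p$score_b),
               auc_a = p$test$auc_a, auc_b = p$test$auc_b,
               delta = p$test$delta, z = p$test$z, p_value = p$test$p_value)
  }))
  rownames(pw_df) <- NULL
  out <- list(flow = object$flow, auc = auc_df, pairwise = pw_df)
  class(out) <- "summary.fevscore_report"
  out
}

#' @export
print.summary.fevscore_report <- function(x, ...) {
  cat("Cohort flow:\n"); print(x$flow)
  cat("\nAUCs:\n"); print(x$auc, row.names = FALSE, digits = 3)
  cat("\nPairwise DeLong tests:\n"); print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot ROC curves for every score in a validation report
#'
#' @param x a `fevscore_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fevscore_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  cols <- seq_along(x$scores) + 1
  for (i in seq_along(x$scores)) {
    sc <- x$scores[i]
    pts <- roc_points(count_scores(x$scored[[sc]], x$scored$outcome))
    graphics::lines(pts$fpr, pts$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = toupper(x$scores), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}

.round2 <- function(x) round_to_resolution(x, 0.01)

.report_as_list <- function(report) {
  auc_list <- function(a) {
    list(auc = a$auc, variance = a$variance, ci_low = a$ci_low,
         ci_high = a$ci_high, cases = a$m, controls = a$n,
         reason = a$reason)
  }
  test_list <- function(p) {
    list(score_a = p$score_a, score_b = p$score_b, auc_a = p$test$auc_a,
         auc_b = p$test$auc_b, delta = p$test$delta, z = p$test$z,
         p_value = p$test$p_value)
  }
  list(
    flow = as.list(report$flow),
    aucs = lapply(report$aucs, auc_list),
    pairwise = lapply(report$pairwise, test_list),
    ladders = report$ladders,
    subgroups = lapply(report$subgroups, function(g) {
      lapply(g, function(lv) lapply(lv, auc_list))
    }),
    sensitivity = lapply(report$sensitivity, function(s) {
      list(aucs = lapply(s$aucs, auc_list),
           pairwise = lapply(s$pairwise, test_list), n = s$n)
    }),
    or_tables = lapply(report$or_tables, function(o) {
      lapply(o, function(tab) as.data.frame(unclass(tab)))
    }),
    conf_level = report$conf.level
  )
}

#' Render a validation report to files
#'
#' Writes `report.json` (machine-readable, full precision, fixed key
#' order), `report.md` (human-readable tables with percentages rounded
#' half-up to 2 dp, blank cells where a statistic is undefined) and one ROC
#' coordinate CSV per score.
#'
#' @param report a `fevscore_report` from [validate_scores()].
#' @param dir destination directory (created if needed).
#' @param formats subset of `c("json", "markdown", "csv")`.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "markdown", "csv")) {
  stopifnot(inherits(report, "fevscore_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(.report_as_list(report), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    files <- c(files, f)
  }
  if ("markdown" %in% formats) {
    f <- file.path(dir, "report.md")
    writeLines(.render_markdown(report), f)
    files <- c(files, f)
  }
  if ("csv" %in% formats) {
    for (sc in report$scores) {
      f <- file.path(dir, paste0("roc_", sc, ".csv"))
      pts <- roc_points(count_scores(report$scored[[sc]],
                                     report$scored$outcome))
      utils::write.csv(pts, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}

.fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", .round2(x)))

.render_markdown <- function(report) {
  lines <- c("# Severity-score validation report", "")
  f <- report$flow
  lines <- c(lines, sprintf(
    "Enrolled %d; lost to follow-up %d; incomplete components %d; analysed %d.",
    f["enrolled"], f["lost_to_follow_up"], f["incomplete_components"],
    f["analysed"]), "")
  lines <- c(lines, "## AUC by score", "",
             "| Score | AUC | CI low | CI high |", "|---|---|---|---|")
  for (sc in report$scores) {
    a <- report$aucs[[sc]]
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", toupper(sc),
                              .fmt2(a$auc), .fmt2(a$ci_low), .fmt2(a$ci_high)))
  }
  lines <- c(lines, "", "## Pairwise DeLong tests", "",
             "| Comparison | AUC a | AUC b | p |", "|---|---|---|---|")
  for (nm in names(report$pairwise)) {
    p <- report$pairwise[[nm]]
    lines <- c(lines, sprintf("| %s | %s | %s | %.3g |", nm,
                              .fmt2(p$test$auc_a), .fmt2(p$test$auc_b),
                              p$test$p_value))
  }
  for (sc in report$scores) {
    lines <- c(lines, "", paste0("## Threshold table: ", toupper(sc)), "",
               "| Threshold | Specificity | Sensitivity | NPV | PPV |",
               "|---|---|---|---|---|")
    lad <- report$ladders[[sc]]
    for (i in seq_len(nrow(lad))) {
      lines <- c(lines, sprintf("| %g | %s | %s | %s | %s |",
                                lad$threshold[i], .fmt2(lad$specificity[i]),
                                .fmt2(lad$sensitivity[i]), .fmt2(lad$npv[i]),
                                .fmt2(lad$ppv[i])))
    }
  }
  lines <- c(lines, "", "## Sensitivity analyses (missing outcome imputed)", "",
             "| Analysis | MEWS | qSOFA | UVA |", "|---|---|---|---|")
  for (mode in names(report$sensitivity)) {
    s <- report$sensitivity[[mode]]
    row <- vapply(c("mews", "qsofa", "uva"), function(sc) {
      a <- s$aucs[[sc]]
      if (is.na(a$auc)) "" else
        sprintf("%s (%s-%s)", .fmt2(a$auc), .fmt2(a$ci_low), .fmt2(a$ci_high))
    }, character(1))
    lines <- c(lines, sprintf("| Missing set to %s | %s | %s | %s |", mode,
                              row[1], row[2], row[3]))
  }
  lines
}
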
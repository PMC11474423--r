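# Logistic regression and descriptive tests: odds-ratio tables with the
# sparse-score-level grouping rule, Pearson chi-squared and tie-corrected
# Mann-Whitney tests.

#' Fit a binomial logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (stats::glm.fit), with Wald standard errors from the inverse
#' observed information, an explicit rank-deficiency error naming the
#' collinear columns, and a perfect-separation diagnostic: when every fitted
#' probability is numerically 0 or 1 the fit is flagged non-converged rather
#' than reported as valid estimates.
#'
#' @param design numeric design matrix or data frame of predictors. An
#'   intercept column is added unless one is present (a constant column
#'   named `(Intercept)`).
#' @param outcome binary outcome: `"alive"`/`"dead"`, 0/1 numeric or logical
#'   (TRUE/1/dead = event).
#' @param tolerance IRLS convergence tolerance on the deviance (default
#'   1e-10).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return an object of class `fevscore_logit` with `coefficients`, `se`,
#'   `vcov`, `converged`, `separation`, `iterations`, `loglik`, `n`,
#'   `fitted`.
#' @export
fit_logistic <- function(design, outcome, tolerance = 1e-10, max_iter = 100) {
  y <- .as_dead(outcome)
  if (is.data.frame(design)) design <- as.matrix(design)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1)
  storage.mode(design) <- "double"
  keep <- stats::complete.cases(design) & !is.na(y)
  design <- design[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  if (!"(Intercept)" %in% colnames(design)) {
    design <- cbind("(Intercept)" = 1, design)
  }
  constant <- apply(design, 2, function(col) length(unique(col)) == 1)
  constant["(Intercept)"] <- FALSE
  if (any(constant)) {
    stop("constant predictor column(s): ",
         paste(colnames(design)[constant], collapse = ", "), call. = FALSE)
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    aliased <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    design, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tolerance, maxit = max_iter)))
  mu <- fit$fitted.values
  eps <- 1e-8
  separation <- all(mu < eps | mu > 1 - eps)
  w <- fit$weights
  info <- crossprod(design * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(design), ncol(design),
           dimnames = list(colnames(design), colnames(design)))
  })
  dimnames(vc) <- list(colnames(design), colnames(design))
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(design)),
    se = sqrt(diag(vc)), vcov = vc,
    converged = fit$converged && !separation,
    separation = separation,
    iterations = fit$iter,
    loglik = -fit$deviance / 2,
    n = length(y), fitted = mu,
    diagnostic = if (separation) {
      "perfect or quasi-perfect separation: all fitted probabilities are 0 or 1; estimates diverge"
    } else NULL
  ), class = "fevscore_logit")
}

#' @export
print.fevscore_logit <- function(x, digits = 4, ...) {
  cat("Logistic regression (IRLS), n =", x$n,
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  print(round(cbind(coef = x$coefficients, se = x$se,
                    OR = exp(x$coefficients)), digits))
  invisible(x)
}

#' @export
coef.fevscore_logit <- function(object, ...) object$coefficients

#' @export
vcov.fevscore_logit <- function(object, ...) object$vcov

#' Odds-ratio table from a fitted logistic model
#'
#' @param fit a `fevscore_logit` object.
#' @param conf.level Wald confidence level (default 0.95).
#' @param reference optional named character vector of reference-level
#'   labels, one per factor predictor, prepended with OR fixed at 1.
#' @return data frame of class `or_table` with columns `term`, `or`,
#'   `ci_low`, `ci_high`, `reference`.
#' @export
or_table <- function(fit, conf.level = 0.95, reference = NULL) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  keep <- names(fit$coefficients) != "(Intercept)"
  est <- fit$coefficients[keep]
  se <- fit$se[keep]
  out <- data.frame(term = names(est), or = exp(est),
                    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
                    reference = FALSE, row.names = NULL)
  if (!is.null(reference)) {
    ref <- data.frame(term = unname(reference), or = 1,
                      ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
    out <- rbind(ref, out)
  }
  class(out) <- c("or_table", "data.frame")
  out
}

#' Group sparse score levels from the top of the scale downward
#'
#' Published practice for modelling ordinal severity scores: score levels
#' with fewer than `min_count` observations in the criterion cell are merged
#' downward (the topmost sparse level is pooled with the level below it)
#' until every retained level meets the minimum. The criterion cell is the
#' total participant count by default; `cell = "dead"` reproduces the
#' alternative reading where fewer than five outcome events triggers
#' grouping.
#'
#' @param counts a [score_counts()] object.
#' @param min_count minimum count per retained level (default 5).
#' @param cell criterion cell: `"total"`, `"dead"` or `"alive"`.
#' @return list with `counts` (grouped [score_counts()], each merged level
#'   labelled by its lowest constituent score) and `mapping` (data frame
#'   `level` -> `grouped_level`, surjective and order-preserving).
#' @export
group_sparse_levels <- function(counts, min_count = 5,
                                cell = c("total", "dead", "alive")) {
  stopifnot(inherits(counts, "score_counts"), min_count >= 1)
  cell <- match.arg(cell)
  crit <- switch(cell, total = counts$alive + counts$dead,
                 dead = counts$dead, alive = counts$alive)
  k <- length(counts$levels)
  group <- seq_len(k)  # group id per original level, non-decreasing
  repeat {
    ids <- unique(group)
    sums <- vapply(ids, function(g) sum(crit[group == g]), numeric(1))
    if (length(ids) == 1) {
      if (sums < min_count) {
        warning("total count below min_count; single-group result",
                call. = FALSE)
      }
      break
    }
    sparse <- ids[sums < min_count]
    if (length(sparse) == 0) break
    # merge the topmost sparse group into the group below it
    g <- max(sparse)
    if (g == min(ids)) {
      # sparse group is the bottom: merge upward instead
      group[group == g] <- min(ids[ids > g])
    } else {
      group[group == g] <- max(ids[ids < g])
    }
  }
  ids <- unique(group)
  new_levels <- vapply(ids, function(g) min(counts$levels[group == g]), numeric(1))
  grouped <- score_counts(
    new_levels,
    alive = vapply(ids, function(g) sum(counts$alive[group == g]), numeric(1)),
    dead = vapply(ids, function(g) sum(counts$dead[group == g]), numeric(1)))
  mapping <- data.frame(level = counts$levels,
                        grouped_level = new_levels[match(group, ids)])
  list(counts = grouped, mapping = mapping)
}

#' Apply a sparse-level grouping to per-subject scores
#'
#' @param score per-subject score values.
#' @param mapping the `mapping` data frame from [group_sparse_levels()].
#' @return grouped score values (lowest constituent score of each group).
#' @export
apply_level_grouping <- function(score, mapping) {
  idx <- match(score, mapping$level)
  out <- mapping$grouped_level[idx]
  out[is.na(score)] <- NA
  out
}

#' Pearson chi-squared test of association for a 2 x k table
#'
#' @param table a matrix of counts (2 rows x k columns).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal total; chi-squared test undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Tie-corrected Mann-Whitney U test
#'
#' U counts the pairs where a value of `x` exceeds a value of `y` (ties
#' count 1/2), so U / (n_x * n_y) is exactly the tie-corrected AUC of `x`
#' against membership of `x` — the test and the ROC machinery share one
#' kernel. The p-value uses the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U`, `auc` (= U / (n_x n_y)), `z`, `p_value`.
#' @export
mann_whitney_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  # shared kernel: treat x as the "case" class
  counts <- count_scores(c(x, y), c(rep(TRUE, nx), rep(FALSE, ny)))
  auc <- auc_mann_whitney(counts)
  U <- auc * nx * ny
  N <- nx + ny
  tie_sizes <- counts$alive + counts$dead
  var_u <- nx * ny / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  z <- if (var_u > 0) (U - nx * ny / 2) / sqrt(var_u) else 0
  list(U = U, auc = auc, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Adjusted (and unadjusted) logistic model for one severity score
#'
#' Fits mortality on the score entered as a categorical factor after
#' sparse-level grouping, optionally adjusted a priori for age group, sex
#' and HIV status. HIV is refused as a covariate for the UVA score because
#' HIV status is a component of that score; the reference score level is 0
#' for qSOFA and UVA and 1 for MEWS.
#'
#' @param cohort cohort data frame with score columns (see
#'   [compute_scores()]) and an `outcome` column.
#' @param score_name `"mews"`, `"qsofa"` or `"uva"` (any score column name).
#' @param covariates character subset of `c("age_group", "sex", "hiv")`;
#'   `character(0)` gives the unadjusted model.
#' @param min_count sparse-level grouping threshold (default 5
#'   participants); see [group_sparse_levels()].
#' @param cell grouping criterion cell, as in [group_sparse_levels()].
#' @param conf.level Wald confidence level.
#' @return an `or_table` with one row per non-reference score level and
#'   covariate level, plus attributes `fit` (the `fevscore_logit`) and
#'   `grouping` (the level mapping).
#' @export
adjusted_model <- function(cohort, score_name,
                           covariates = c("age_group", "sex", "hiv"),
                           min_count = 5, cell = "total", conf.level = 0.95) {
  if (length(covariates)) {
    covariates <- match.arg(covariates, several.ok = TRUE)
  }
  if (length(covariates) && score_name == "uva" && "hiv" %in% covariates) {
    stop("HIV status is a component of the UVA score and cannot be an ",
         "adjustment covariate for it", call. = FALSE)
  }
  if (!score_name %in% names(cohort)) {
    stop("no column '", score_name, "' in cohort; run compute_scores() first",
         call. = FALSE)
  }
  dead <- .as_dead(cohort$outcome)
  keep <- !is.na(dead) & !is.na(cohort[[score_name]])
  if ("age_group" %in% covariates) keep <- keep & !is.na(cohort$age_years)
  if ("sex" %in% covariates) keep <- keep & !is.na(cohort$sex)
  if ("hiv" %in% covariates) {
    keep <- keep & !is.na(cohort$hiv_status) & cohort$hiv_status != "unknown"
  }
  d <- cohort[keep, , drop = FALSE]
  dead <- dead[keep]

  grp <- group_sparse_levels(count_scores(d[[score_name]], dead),
                             min_count = min_count, cell = cell)
  grouped <- apply_level_grouping(d[[score_name]], grp$mapping)
  ref_level <- if (score_name == "mews") 1 else 0
  lv <- sort(unique(grouped))
  if (!ref_level %in% lv) ref_level <- lv[1]
  score_f <- factor(grouped, levels = c(ref_level, setdiff(lv, ref_level)))

  design <- stats::model.matrix(~score_f)[, -1, drop = FALSE]
  colnames(design) <- paste0(score_name, "=", levels(score_f)[-1])
  ref_labels <- paste0(score_name, "=", ref_level)
  if ("age_group" %in% covariates) {
    ag <- age_group(d$age_years)
    mm <- stats::model.matrix(~ag)[, -1, drop = FALSE]
    colnames(mm) <- paste0("age=", levels(ag)[-1])
    design <- cbind(design, mm)
    ref_labels <- c(ref_labels, paste0("age=", levels(ag)[1]))
  }
  if ("sex" %in% covariates) {
    design <- cbind(design, "sex=male" = as.numeric(d$sex == "male"))
    ref_labels <- c(ref_labels, "sex=female")
  }
  if ("hiv" %in% covariates) {
    design <- cbind(design, "hiv=positive" = as.numeric(d$hiv_status == "positive"))
    ref_labels <- c(ref_labels, "hiv=negative")
  }
  fit <- fit_logistic(design, dead, tolerance = 1e-10)
  out <- or_table(fit, conf.level = conf.level, reference = ref_labels)
  attr(out, "fit") <- fit
  attr(out, "grouping") <- grp$mapping
  out
}

#' Standard six-level adult age grouping
#'
#' Age in years mapped to the bands 15-<25, 25-<35, 35-<45, 45-<55, 55-<65,
#' 65+, reference 15-<25.
#'
#' @param age_years numeric age in years.
#' @return ordered factor of age bands.
#' @export
age_group <- function(age_years) {
  cut(age_years, breaks = c(15, 25, 35, 45, 55, 65, Inf),
      labels = c("15-<25", "25-<35", "35-<45", "45-<55", "55-<65", "65+"),
      right = FALSE, include.lowest = TRUE)
}
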
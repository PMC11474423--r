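# ScoreCounts: per-score-level alive/dead counts, the sufficient statistic
# for all ROC computation on an ordinal score.

#' Per-level alive/dead counts for an ordinal score
#'
#' @param levels strictly increasing numeric score values.
#' @param alive non-negative integer count of survivors at each level.
#' @param dead non-negative integer count of deaths at each level.
#' @return an object of class `score_counts`.
#' @examples
#' score_counts(0:3, alive = c(1387, 1047, 176, 2), dead = c(49, 79, 50, 7))
#' @export
score_counts <- function(levels, alive, dead) {
  levels <- as.numeric(levels)
  alive <- as.numeric(alive)
  dead <- as.numeric(dead)
  if (length(levels) != length(alive) || length(levels) != length(dead)) {
    stop("levels, alive and dead must have equal length", call. = FALSE)
  }
  if (any(is.na(levels)) || is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing and non-missing", call. = FALSE)
  }
  if (any(is.na(alive)) || any(is.na(dead)) ||
      any(alive < 0) || any(dead < 0) ||
      any(alive != floor(alive)) || any(dead != floor(dead))) {
    stop("alive and dead must be non-negative integers", call. = FALSE)
  }
  structure(list(levels = levels, alive = alive, dead = dead),
            class = "score_counts")
}

#' Tabulate per-subject scores and outcomes into score counts
#'
#' @param score per-subject ordinal score values.
#' @param outcome per-subject outcome, `"alive"`/`"dead"` character or
#'   0/1 numeric (1 = dead) or logical (TRUE = dead).
#' @return a [score_counts()] object over the observed levels.
#' @export
count_scores <- function(score, outcome) {
  if (length(score) != length(outcome)) {
    stop("score and outcome must have equal length", call. = FALSE)
  }
  dead <- .as_dead(outcome)
  keep <- !is.na(score) & !is.na(dead)
  score <- score[keep]; dead <- dead[keep]
  lv <- sort(unique(score))
  score_counts(lv,
               alive = vapply(lv, function(l) sum(score == l & !dead), numeric(1)),
               dead  = vapply(lv, function(l) sum(score == l & dead), numeric(1)))
}

.as_dead <- function(outcome) {
  if (is.character(outcome) || is.factor(outcome)) {
    outcome <- as.character(outcome)
    out <- rep(NA, length(outcome))
    out[outcome == "dead"] <- TRUE
    out[outcome == "alive"] <- FALSE
    bad <- !is.na(outcome) & !(outcome %in% c("alive", "dead", "missing"))
    if (any(bad)) {
      stop("outcome values must be 'alive', 'dead' or 'missing'", call. = FALSE)
    }
    out
  } else {
    as.logical(outcome)
  }
}

#' @export
print.score_counts <- function(x, ...) {
  cat("Score counts:", sum(x$dead), "dead /", sum(x$alive), "alive over",
      length(x$levels), "levels\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.score_counts <- function(x, ...) {
  data.frame(level = x$levels, alive = x$alive, dead = x$dead)
}

#' Read or write score counts as CSV
#'
#' CSV columns are `level`, `alive`, `dead`, one row per score level.
#'
#' @param path file path.
#' @return [read_score_counts()] returns a `score_counts` object;
#'   [write_score_counts()] returns `path` invisibly.
#' @export
read_score_counts <- function(path) {
  d <- utils::read.csv(path)
  need <- c("level", "alive", "dead")
  if (!all(need %in% names(d))) {
    stop("score-counts CSV must have columns level, alive, dead", call. = FALSE)
  }
  score_counts(d$level, d$alive, d$dead)
}

#' @rdname read_score_counts
#' @param counts a [score_counts()] object.
#' @export
write_score_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}
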
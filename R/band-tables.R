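#' @importFrom stats qnorm pnorm var plogis rbinom rnorm runif rexp rlnorm
#' @importFrom utils read.csv write.csv
NULL

# A score band table is a data-driven description of one severity score:
# for each component either an ordered set of closed numeric intervals
# (at a stated measurement resolution) mapping to points, or a discrete
# category -> points map. Interval bounds are stored inclusive at the
# component's resolution so disjointness/coverage can be checked exactly
# on the measurement grid.

.interval_component <- function(unit, resolution, range_lo, range_hi, bands) {
  bands_df <- do.call(rbind, lapply(bands, function(b) {
    data.frame(lo = b[[1]], hi = b[[2]], points = b[[3]])
  }))
  list(type = "interval", unit = unit, resolution = resolution,
       range = c(range_lo, range_hi), bands = bands_df)
}

.category_component <- function(map) {
  list(type = "category",
       levels = names(map),
       points = as.integer(unname(map)))
}

#' Default MEWS component band table
#'
#' The Modified Early Warning Score sums points from body temperature, heart
#' rate, respiratory rate, systolic blood pressure and the AVPU consciousness
#' level. Band boundaries falling in gaps of the published instrument are
#' closed by extending the more-severe band to the boundary (heart rate 40
#' scores 2, SBP 70 scores 3, respiratory rate 8 scores 2) so a sicker
#' patient is never under-scored. SBP at or above 200 scores 2 per the
#' standard MEWS instrument. The component maximum is 14 even though the
#' instrument is conventionally described as ranging 0-11; the discrepancy is
#' in the published band definitions themselves and is reproduced, not
#' reconciled.
#'
#' @return A score band table object (list with `name`, `components`,
#'   `max_points`).
#' @seealso [qsofa_band_table()], [uva_band_table()], [score_mews()]
#' @export
mews_band_table <- function() {
  structure(list(
    name = "mews",
    components = list(
      temperature = .interval_component("degC", 0.1, 25, 45, list(
        list(-Inf, 34.9, 2L),
        list(35.0, 38.4, 0L),
        list(38.5, Inf, 2L))),
      heart_rate = .interval_component("bpm", 1, 0, 300, list(
        list(-Inf, 40, 2L),
        list(41, 50, 1L),
        list(51, 100, 0L),
        list(101, 110, 1L),
        list(111, 129, 2L),
        list(130, Inf, 3L))),
      resp_rate = .interval_component("brpm", 1, 0, 90, list(
        list(-Inf, 8, 2L),
        list(9, 14, 0L),
        list(15, 20, 1L),
        list(21, 29, 2L),
        list(30, Inf, 3L))),
      sbp = .interval_component("mmHg", 1, 0, 300, list(
        list(-Inf, 70, 3L),
        list(71, 80, 2L),
        list(81, 100, 1L),
        list(101, 199, 0L),
        list(200, Inf, 2L))),
      avpu = .category_component(c(A = 0L, V = 1L, P = 2L, U = 3L))
    ),
    max_points = 14L
  ), class = "score_band_table")
}

#' Default qSOFA component band table
#'
#' One point each for respiratory rate >= 22 breaths/min, systolic blood
#' pressure <= 100 mmHg, and Glasgow Coma Scale below 15.
#'
#' @return A score band table object.
#' @seealso [mews_band_table()], [uva_band_table()], [score_qsofa()]
#' @export
qsofa_band_table <- function() {
  structure(list(
    name = "qsofa",
    components = list(
      resp_rate = .interval_component("brpm", 1, 0, 90, list(
        list(-Inf, 21, 0L),
        list(22, Inf, 1L))),
      sbp = .interval_component("mmHg", 1, 0, 300, list(
        list(-Inf, 100, 1L),
        list(101, Inf, 0L))),
      gcs = .interval_component("points", 1, 3, 15, list(
        list(-Inf, 14, 1L),
        list(15, 15, 0L)))
    ),
    max_points = 3L
  ), class = "score_band_table")
}

#' Default UVA component band table
#'
#' The Universal Vital Assessment score: temperature below 36 scores 2, heart
#' rate >= 120 scores 1, respiratory rate >= 30 scores 1, SBP below 90 scores
#' 1, oxygen saturation below 92 scores 2, GCS below 15 scores 4, and
#' HIV-positive status scores 2 (negative and unknown both score 0). The
#' component maximum is 13 although the instrument is conventionally
#' described as 0-12; as with MEWS the published bands are reproduced
#' faithfully.
#'
#' @return A score band table object.
#' @seealso [mews_band_table()], [qsofa_band_table()], [score_uva()]
#' @export
uva_band_table <- function() {
  structure(list(
    name = "uva",
    components = list(
      temperature = .interval_component("degC", 0.1, 25, 45, list(
        list(-Inf, 35.9, 2L),
        list(36.0, Inf, 0L))),
      heart_rate = .interval_component("bpm", 1, 0, 300, list(
        list(-Inf, 119, 0L),
        list(120, Inf, 1L))),
      resp_rate = .interval_component("brpm", 1, 0, 90, list(
        list(-Inf, 29, 0L),
        list(30, Inf, 1L))),
      sbp = .interval_component("mmHg", 1, 0, 300, list(
        list(-Inf, 89, 1L),
        list(90, Inf, 0L))),
      spo2 = .interval_component("pct", 1, 0, 100, list(
        list(-Inf, 91, 2L),
        list(92, Inf, 0L))),
      gcs = .interval_component("points", 1, 3, 15, list(
        list(-Inf, 14, 4L),
        list(15, 15, 0L))),
      hiv = .category_component(c(positive = 2L, negative = 0L, unknown = 0L))
    ),
    max_points = 13L
  ), class = "score_band_table")
}

#' Round half away from zero at a given resolution
#'
#' Measurements are rounded half-up to the component's resolution before
#' banding so non-grid inputs band deterministically (R's `round()` rounds
#' half to even, which would make banding depend on the parity of the
#' neighbouring grid value).
#'
#' @param x numeric vector.
#' @param resolution grid spacing (e.g. 1 for integer vitals, 0.1 for
#'   temperature).
#' @return `x` rounded to the nearest multiple of `resolution`, ties away
#'   from zero.
#' @export
round_to_resolution <- function(x, resolution = 1) {
  sign(x) * floor(abs(x) / resolution + 0.5) * resolution
}

# Look up points for one interval component; x already validated/rounded.
.band_points <- function(component, x) {
  b <- component$bands
  out <- rep(NA_integer_, length(x))
  eps <- component$resolution / 2
  for (k in seq_len(nrow(b))) {
    hit <- x >= b$lo[k] - eps & x <= b$hi[k] + eps
    out[hit] <- b$points[k]
  }
  out
}

.category_points <- function(component, x) {
  idx <- match(as.character(x), component$levels)
  component$points[idx]
}

#' Points allocated by one component of a score band table
#'
#' @param table a score band table, e.g. [mews_band_table()].
#' @param component component name (e.g. `"heart_rate"`).
#' @param x measurement values (numeric for interval components, character or
#'   factor for category components).
#' @return integer vector of points; `NA` where `x` is `NA`.
#' @export
component_points <- function(table, component, x) {
  comp <- table$components[[component]]
  if (is.null(comp)) {
    stop("unknown component '", component, "' in score table '", table$name, "'")
  }
  if (comp$type == "interval") {
    x <- round_to_resolution(as.numeric(x), comp$resolution)
    .band_points(comp, x)
  } else {
    .category_points(comp, x)
  }
}

#' Validate a score band table
#'
#' Checks that, for every interval component, the bands are disjoint and
#' jointly cover the component's valid measurement range on the resolution
#' grid (no value can fall through or match twice), and that all points are
#' non-negative integers.
#'
#' @param table a score band table.
#' @return `TRUE` invisibly; otherwise an error naming the offending
#'   component.
#' @export
validate_band_table <- function(table) {
  stopifnot(inherits(table, "score_band_table"))
  for (nm in names(table$components)) {
    comp <- table$components[[nm]]
    if (any(is.na(comp[["points"]] %||% comp$bands$points)) ||
        any((comp[["points"]] %||% comp$bands$points) < 0)) {
      stop("component '", nm, "': points must be non-negative")
    }
    if (comp$type != "interval") next
    grid <- seq(comp$range[1], comp$range[2], by = comp$resolution)
    grid <- round_to_resolution(grid, comp$resolution)
    eps <- comp$resolution / 2
    hits <- vapply(grid, function(g) {
      sum(g >= comp$bands$lo - eps & g <= comp$bands$hi + eps)
    }, integer(1))
    if (any(hits == 0)) {
      stop("component '", nm, "': value ", grid[which(hits == 0)[1]],
           " is covered by no band")
    }
    if (any(hits > 1)) {
      stop("component '", nm, "': value ", grid[which(hits > 1)[1]],
           " is covered by ", max(hits), " bands")
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a score band table to JSON
#'
#' The serialisation keeps interval bounds, resolutions and points exactly so
#' a table can be pinned bit-for-bit in configuration or tests.
#'
#' @param table a score band table.
#' @param path file path to write.
#' @return `path` invisibly.
#' @export
write_band_table <- function(table, path) {
  obj <- list(name = table$name, max_points = table$max_points,
              components = lapply(table$components, function(comp) {
                if (comp$type == "interval") {
                  b <- comp$bands
                  # JSON has no +/-Inf; serialise bounds as strings
                  b$lo <- as.character(b$lo)
                  b$hi <- as.character(b$hi)
                  list(type = "interval", unit = comp$unit,
                       resolution = comp$resolution,
                       range = comp$range,
                       bands = b)
                } else {
                  list(type = "category", levels = comp$levels,
                       points = comp$points)
                }
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a score band table from JSON
#'
#' @param path file written by [write_band_table()].
#' @return a validated score band table.
#' @export
read_band_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(obj$components, function(comp) {
    if (comp$type == "interval") {
      b <- as.data.frame(comp$bands)
      b$lo <- as.numeric(b$lo); b$hi <- as.numeric(b$hi)
      b$points <- as.integer(b$points)
      list(type = "interval", unit = comp$unit,
           resolution = as.numeric(comp$resolution),
           range = as.numeric(comp$range), bands = b)
    } else {
      list(type = "category", levels = as.character(comp$levels),
           points = as.integer(comp$points))
    }
  })
  tab <- structure(list(name = obj$name, components = comps,
                        max_points = as.integer(obj$max_points)),
                   class = "score_band_table")
  validate_band_table(tab)
  tab
}

#' @export
print.score_band_table <- function(x, ...) {
  cat("Score band table:", x$name, " (max ", x$max_points, " points)\n", sep = "")
  for (nm in names(x$components)) {
    comp <- x$components[[nm]]
    if (comp$type == "interval") {
      bands <- apply(comp$bands, 1, function(b) {
        sprintf("[%s, %s]=%s", b[["lo"]], b[["hi"]], b[["points"]])
      })
      cat("  ", nm, " (", comp$unit, "): ", paste(bands, collapse = " "), "\n", sep = "")
    } else {
      cat("  ", nm, ": ",
          paste(sprintf("%s=%d", comp$levels, comp$points), collapse = " "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
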
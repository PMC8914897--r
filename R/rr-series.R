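#' RR-interval time series
#'
#' An `rr_series` is a tibble with two columns: `time` (seconds since recording
#' start, strictly increasing, interpreted as the instant of the beat *ending*
#' the interval) and `rr` (the interval in seconds, one per beat). An optional
#' free-text condition label (e.g. `"stress"`, `"relax"`) travels as an
#' attribute. On a clean recording the two columns are redundant:
#' `rr[i] == time[i] - time[i-1]` at every adjacent pair (the
#' abscissa-ordinate equality); departures from that equality are exactly what
#' the filtering and imputation functions detect and repair.
#'
#' @param time Numeric vector of beat timestamps in seconds, strictly
#'   increasing.
#' @param rr Numeric vector of RR intervals in seconds, same length as `time`,
#'   all positive. If missing, intervals are reconstructed as
#'   `diff(c(0, time))`, which yields a fully consistent series.
#' @param label Optional condition tag stored as an attribute.
#'
#' @return A tibble of class `rr_series` with columns `time` and `rr`.
#' @examples
#' rr_series(time = cumsum(c(0.8, 0.9, 0.85)))
#' @export
rr_series <- function(time, rr = NULL, label = NULL) {
  if (is.null(rr)) rr <- diff(c(0, time))
  out <- tibble::tibble(time = as.numeric(time), rr = as.numeric(rr))
  new_rr_series(out, label = label, validate = TRUE)
}

new_rr_series <- function(df, label = NULL, validate = FALSE,
                          subclass = character()) {
  out <- tibble::as_tibble(df[, c("time", "rr")])
  class(out) <- c(subclass, "rr_series", class(tibble::tibble()))
  attr(out, "label") <- label
  if (validate) validate_rr_series(out)
  out
}

validate_rr_series <- function(x) {
  if (!all(c("time", "rr") %in% names(x))) {
    stop("an rr_series needs `time` and `rr` columns", call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$time) || anyNA(x$rr)) {
    stop("rr_series contains missing values", call. = FALSE)
  }
  if (any(diff(x$time) <= 0)) {
    bad <- which(diff(x$time) <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing (violated at beat %d)",
                 bad), call. = FALSE)
  }
  if (any(x$rr <= 0)) {
    stop("all RR intervals must be positive", call. = FALSE)
  }
  invisible(x)
}

#' Coerce to an RR series
#'
#' @param x A data frame with `time` and `rr` columns (or a bare numeric vector
#'   of intervals).
#' @param label Optional condition tag; defaults to the existing attribute.
#' @return An `rr_series` tibble.
#' @export
as_rr_series <- function(x, label = NULL) {
  if (is.numeric(x)) return(rr_series(time = cumsum(x), rr = x, label = label))
  new_rr_series(x, label = label %||% attr(x, "label"), validate = TRUE)
}

#' @export
print.rr_series <- function(x, ...) {
  lab <- attr(x, "label")
  dur <- if (nrow(x)) max(x$time) else 0
  cat(sprintf("# An RR series: %d beats, %.1f s%s\n", nrow(x), dur,
              if (!is.null(lab)) paste0(", label: ", lab) else ""))
  NextMethod()
}

#' Condition label of an RR series
#' @param x An `rr_series`.
#' @return The label attribute (or `NULL`).
#' @export
rr_label <- function(x) attr(x, "label")

#' Physiological bounds and deviation policy
#'
#' Container for the physiological constraints driving filtering and
#' imputation: intervals shorter than `rr_min` (default 0.3 s) are treated as
#' spurious extra detections to be merged, intervals longer than `rr_max`
#' (default 1.3 s) as missed beats to be deleted; `max_deviation` (default
#' 0.4, i.e. 40%) caps the local successive-difference budget used to accept a
#' repaired beat; `lookback` (default 10) is how many preceding intervals feed
#' the local statistics (deviation budget, Gaussian fit, gap-size estimate).
#'
#' @param rr_min,rr_max Physiological interval bounds in seconds.
#' @param max_deviation Cap on the local mean successive relative difference,
#'   a dimensionless fraction in (0, 1].
#' @param lookback Number of preceding intervals used for local statistics.
#' @return A list of class `physio_bounds`.
#' @examples
#' physio_bounds()
#' physio_bounds(rr_max = 1.5)
#' @export
physio_bounds <- function(rr_min = 0.3, rr_max = 1.3,
                          max_deviation = 0.4, lookback = 10L) {
  stopifnot(rr_min > 0, rr_min < rr_max,
            max_deviation > 0, max_deviation <= 1, lookback >= 1)
  structure(list(rr_min = rr_min, rr_max = rr_max,
                 max_deviation = max_deviation,
                 lookback = as.integer(lookback)),
            class = "physio_bounds")
}

#' @export
print.physio_bounds <- function(x, ...) {
  cat(sprintf(
    "physiological bounds: [%.3g, %.3g] s, deviation cap %.2g, lookback %d\n",
    x$rr_min, x$rr_max, x$max_deviation, x$lookback))
  invisible(x)
}

#' Read physiological bounds from a JSON configuration file
#'
#' The file maps any subset of `rr_min`, `rr_max`, `max_deviation`, `lookback`
#' to numbers; unspecified fields keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `physio_bounds` object.
#' @export
read_physio_bounds <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("rr_min", "rr_max", "max_deviation", "lookback")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown bounds field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(physio_bounds, cfg[intersect(known, names(cfg))])
}

#' Read an RR series from a delimited text file
#'
#' Two dialects are supported. `"two-column"` files carry one
#' `timestamp, interval` record per line; `"intervals-only"` files carry one
#' interval per line and timestamps are reconstructed by cumulative sum (the
#' first beat is placed at its own interval), which makes the result fully
#' consistent by construction. Fields may be separated by commas or
#' whitespace; lines starting with `#` are ignored. `dialect = "auto"` picks
#' by the number of fields on the first data line.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"two-column"`, `"intervals-only"`.
#' @param units `"s"` (default) or `"ms"`; millisecond input is divided by
#'   1000 on ingest so the in-memory canon is always seconds.
#' @param label Optional condition tag attached to the result.
#' @return An `rr_series` tibble.
#' @export
read_rr_series <- function(path,
                           dialect = c("auto", "two-column", "intervals-only"),
                           units = c("s", "ms"), label = NULL) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(rr_series(numeric(0), numeric(0), label = label))

  fields <- strsplit(trimws(lines), "[,;[:space:]]+")
  nf <- lengths(fields)
  if (dialect == "auto") dialect <- if (nf[1] >= 2) "two-column" else "intervals-only"
  want <- if (dialect == "two-column") 2L else 1L
  bad <- which(nf != want)
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- sort(union(bad, which(vapply(vals, anyNA, logical(1)))))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: '%s'",
                 lineno[bad[1]], path, lines[bad[1]]), call. = FALSE)
  }
  scale <- if (units == "ms") 1e-3 else 1
  m <- matrix(unlist(vals), ncol = want, byrow = TRUE) * scale
  if (dialect == "two-column") {
    rr_series(time = m[, 1], rr = m[, 2], label = label)
  } else {
    rr_series(time = cumsum(m[, 1]), rr = m[, 1], label = label)
  }
}

#' Write an RR series to a delimited text file
#'
#' @param series An `rr_series`.
#' @param path Output path.
#' @param dialect `"two-column"` (timestamp and interval, the lossless form)
#'   or `"intervals-only"` (intervals alone; only lossless for fully
#'   consistent series).
#' @param digits Significant digits written (default 15, round-trips doubles
#'   well below the 1e-9 s consistency tolerance).
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(series, path, dialect = c("two-column", "intervals-only"),
                            digits = 15) {
  dialect <- match.arg(dialect)
  series <- as_rr_series(series)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  lines <- if (dialect == "two-column") {
    paste(fmt(series$time), fmt(series$rr), sep = ",")
  } else {
    fmt(series$rr)
  }
  writeLines(c("# time_s,rr_s"[dialect == "two-column"], lines), path)
  invisible(path)
}

#' Locate violations of the timestamp-interval equality
#'
#' Reports every beat position `i >= 2` where the recorded interval disagrees
#' with the timestamp difference to the previous beat,
#' `|rr[i] - (time[i] - time[i-1])| > tol`, *and* the timestamp difference is
#' at most `rr_max`. Larger timestamp differences are gaps — lost beats — and
#' are reported by [detect_gaps()] instead, so the two diagnostics partition
#' the ways a series can depart from full consistency.
#'
#' @param series An `rr_series`.
#' @param tol Tolerance in seconds (default 1e-9; the arithmetic is exact up
#'   to float noise).
#' @param bounds A [physio_bounds()] object supplying `rr_max`.
#' @return Integer vector of violating beat positions (1-based; empty when the
#'   series is fully consistent).
#' @examples
#' s <- rr_series(time = c(1, 2), rr = c(1, 0.7))
#' check_consistency(s) # beat 2 disagrees: 2 - 1 != 0.7
#' @export
check_consistency <- function(series, tol = 1e-9, bounds = physio_bounds()) {
  series <- as_rr_series(series)
  if (nrow(series) < 2) return(integer(0))
  dt <- diff(series$time)
  bad <- abs(series$rr[-1] - dt) > tol & dt <= bounds$rr_max + tol
  which(bad) + 1L
}
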
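#' Estimate how many beats a gap should contain
#'
#' The interpolation baselines need to know how many placeholder beats to
#' insert: the gap duration divided by the mean of the `lookback` intervals
#' preceding the gap, rounded down. (A gap at the series start falls back to
#' the intervals after it, as in [fit_local_gaussian()].)
#'
#' @param gap One row of [detect_gaps()] output.
#' @param series The `rr_series` containing the gap.
#' @param bounds A [physio_bounds()] object.
#' @return A non-negative integer count.
#' @examples
#' s <- rr_series(time = c(cumsum(rep(0.8, 5)), 4 + 4.0), rr = c(rep(0.8, 5), 0.8))
#' estimate_gap_count(detect_gaps(s)[1, ], s) # floor(4.0 / 0.8) = 5
#' @export
estimate_gap_count <- function(gap, series, bounds = physio_bounds()) {
  series <- as_rr_series(series)
  tol <- 1e-9
  src <- tail(series$rr[series$time <= gap$t_start + tol], bounds$lookback)
  if (!length(src)) {
    src <- head(series$rr[series$time >= gap$t_end - tol], bounds$lookback)
  }
  m <- if (length(src)) mean(src) else 0.8
  # 1e-9 guard so float noise cannot pull an exact quotient below its floor
  as.integer(floor((gap$t_end - gap$t_start) / m + 1e-9))
}

#' Fill gaps by 1-D interpolation of the tachogram (baseline methods)
#'
#' The standard alternative to [impute_dvc()]: for each gap,
#' [estimate_gap_count()] placeholder beats are laid at equally spaced
#' timestamps inside the gap and their interval values are read off a 1-D
#' interpolant of interval versus timestamp fitted to all valid beats of the
#' series. `"linear"` uses straight segments, `"pchip"` a shape-preserving
#' piecewise cubic, `"spline"` a cubic spline with not-a-knot end conditions.
#' No consistency repair is performed: interpolated values need not equal
#' their timestamp differences, and spline values may even leave the
#' physiological bounds — deliberately so, since breaking the
#' timestamp-interval dependence is precisely the weakness of these methods
#' that the DVC approach addresses. `"deletion"` inserts nothing and returns
#' the gappy series as-is.
#'
#' @param series An `rr_series` with gaps.
#' @param method One of `"linear"`, `"pchip"`, `"spline"`, `"deletion"`.
#' @param bounds A [physio_bounds()] object.
#' @return The series with placeholders inserted (class `rr_interpolated`),
#'   with a per-gap log attached ([tidy()]): the method actually used (fewer
#'   support beats than the interpolant needs — 2 for linear, 4 for
#'   pchip/spline — falls back to linear), the number of beats inserted, and
#'   how many inserted values fell outside the physiological bounds.
#' @export
impute_interpolation <- function(series,
                                 method = c("linear", "pchip", "spline", "deletion"),
                                 bounds = physio_bounds()) {
  method <- match.arg(method)
  series <- as_rr_series(series)
  gaps <- detect_gaps(series, bounds)
  logs <- list()
  pieces <- list(series[, c("time", "rr")])
  sup_t <- series$time
  sup_rr <- series$rr
  need <- c(linear = 2L, pchip = 4L, spline = 4L, deletion = 0L)[[method]]

  for (g in seq_len(nrow(gaps))) {
    gap <- gaps[g, ]
    n_ins <- if (method == "deletion") 0L else estimate_gap_count(gap, series, bounds)
    used <- method
    if (n_ins > 0L) {
      t_new <- gap$t_start + seq_len(n_ins) * (gap$t_end - gap$t_start) / (n_ins + 1)
      if (length(sup_t) < need) used <- "linear"
      v <- switch(used,
        linear = approx(sup_t, sup_rr, xout = t_new, rule = 2)$y,
        pchip = pracma::pchip(sup_t, sup_rr, t_new),
        spline = spline_notaknot(sup_t, sup_rr, t_new)
      )
      pieces[[length(pieces) + 1L]] <- tibble::tibble(time = t_new, rr = v)
    } else {
      v <- numeric(0)
    }
    logs[[g]] <- tibble::tibble(
      !!!gap[, c("gap", "t_start", "t_end")], method = used,
      n_inserted = n_ins,
      n_outside_bounds = sum(v < bounds$rr_min | v > bounds$rr_max))
  }
  df <- dplyr::arrange(dplyr::bind_rows(pieces), .data$time)
  out <- new_rr_series(df, label = rr_label(series),
                       subclass = "rr_interpolated")
  attr(out, "interp_log") <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(gap = integer(0), t_start = numeric(0), t_end = numeric(0),
                   method = character(0), n_inserted = integer(0),
                   n_outside_bounds = integer(0))
  attr(out, "method") <- method
  out
}

#' @method tidy rr_interpolated
#' @export
tidy.rr_interpolated <- function(x, ...) attr(x, "interp_log")

#' @method glance rr_interpolated
#' @export
glance.rr_interpolated <- function(x, ...) {
  lg <- attr(x, "interp_log")
  tibble::tibble(method = attr(x, "method"), n_beats = nrow(x),
                 n_gaps = nrow(lg), n_inserted = sum(lg$n_inserted),
                 n_outside_bounds = sum(lg$n_outside_bounds))
}

# cubic spline interpolation with not-a-knot end conditions (the common
# default in numerical libraries; no installed R interpolator offers it).
# Solves the tridiagonal moment system with third-derivative continuity
# imposed at the second and second-to-last knots.
spline_notaknot <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  h <- diff(x)
  i <- seq(2L, n - 1L)
  rows <- c(i, i, i)
  cols <- c(i - 1L, i, i + 1L)
  vals <- c(h[i - 1L], 2 * (h[i - 1L] + h[i]), h[i])
  rhs <- numeric(n)
  rhs[i] <- 6 * ((y[i + 1L] - y[i]) / h[i] - (y[i] - y[i - 1L]) / h[i - 1L])
  # not-a-knot: S''' continuous at x[2] and x[n-1]
  rows <- c(rows, 1L, 1L, 1L, n, n, n)
  cols <- c(cols, 1L, 2L, 3L, n - 2L, n - 1L, n)
  vals <- c(vals, h[2L], -(h[1L] + h[2L]), h[1L],
            h[n - 1L], -(h[n - 2L] + h[n - 1L]), h[n - 2L])
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  M <- as.numeric(Matrix::solve(A, rhs))

  idx <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  hi <- h[idx]
  a <- (x[idx + 1L] - xout) / hi
  b <- (xout - x[idx]) / hi
  a * y[idx] + b * y[idx + 1L] +
    ((a^3 - a) * M[idx] + (b^3 - b) * M[idx + 1L]) * hi^2 / 6
}
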
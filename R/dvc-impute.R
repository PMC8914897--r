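#' Detect gaps in an RR series
#'
#' A gap is an adjacency whose timestamp difference exceeds the maximum
#' physiological interval `rr_max`: more time elapsed between two recorded
#' beats than a single heartbeat can span, so at least one beat was lost
#' (dropped by the sensor or deleted by [filter_ectopics()]). Smaller
#' timestamp/interval mismatches are not gaps; they are reported by
#' [check_consistency()].
#'
#' @param series An `rr_series`.
#' @param bounds A [physio_bounds()] object.
#' @param tol Tolerance in seconds.
#' @return A tibble with one row per gap, ordered by `t_start`: `gap` (ordinal),
#'   `t_start` (last valid timestamp before the gap), `t_end` (first valid
#'   timestamp after it), `rr_end` (the interval recorded at `t_end`), and
#'   `span = t_end - t_start`.
#' @examples
#' s <- rr_series(time = c(1.0, 1.8, 6.0), rr = c(1.0, 0.8, 0.8))
#' detect_gaps(s)
#' @export
detect_gaps <- function(series, bounds = physio_bounds(), tol = 1e-9) {
  series <- as_rr_series(series)
  if (nrow(series) < 2) {
    return(tibble::tibble(gap = integer(0), t_start = numeric(0),
                          t_end = numeric(0), rr_end = numeric(0),
                          span = numeric(0)))
  }
  dt <- diff(series$time)
  at <- which(dt > bounds$rr_max + tol)
  tibble::tibble(gap = seq_along(at),
                 t_start = series$time[at],
                 t_end = series$time[at + 1L],
                 rr_end = series$rr[at + 1L],
                 span = dt[at])
}

#' Fit the local Gaussian used to fill a gap
#'
#' Sample mean and standard deviation (n-1 denominator) of up to
#' `bounds$lookback` intervals ending at the gap's start — the heart's
#' short-term variability just before signal loss, which the fill then
#' reproduces. A gap at the very start of the series (nothing before it) falls
#' back to the intervals just *after* the gap; a series with no usable data on
#' either side falls back to documented defaults (mu = 0.8 s, sigma = 0.05 s,
#' a typical resting adult).
#'
#' @param series An `rr_series`.
#' @param gap One row of [detect_gaps()] output (or a list with `t_start`,
#'   `t_end`).
#' @param bounds A [physio_bounds()] object.
#' @return A list with `mu`, `sigma` (seconds; `sigma = 0` when only one
#'   source interval exists) and `n_source`.
#' @export
fit_local_gaussian <- function(series, gap, bounds = physio_bounds()) {
  series <- as_rr_series(series)
  tol <- 1e-9
  src <- tail(series$rr[series$time <= gap$t_start + tol], bounds$lookback)
  if (!length(src)) {
    src <- head(series$rr[series$time >= gap$t_end - tol], bounds$lookback)
  }
  if (!length(src)) {
    return(list(mu = 0.8, sigma = 0.05, n_source = 0L))
  }
  list(mu = mean(src),
       sigma = if (length(src) >= 2) sd(src) else 0,
       n_source = length(src))
}

#' Fill one gap by backward insertion of Gaussian-sampled intervals
#'
#' Beats are inserted from the end of the gap towards its start, so that every
#' inserted interval equals the difference of its two timestamps by
#' construction. The first insertion point is `t_end - rr_end`; each sampled
#' interval `rr ~ N(mu, sigma^2)` must lie within the physiological bounds and
#' deviate from its already-inserted successor by no more than the local
#' deviation budget (rejection sampling; after 1000 rejections the draw is
#' clamped into the intersection of the bounds and `mu +/- 2 sigma`). When the
#' remaining span to `t_start` drops below `rr_max`, the closing interval is
#' set deterministically to that residual and validated against the bounds and
#' both neighbours' deviations; on failure the last two insertions are removed
#' and resampled, and after every four failed closings the deviation budget is
#' raised by 5 percentage points, which guarantees convergence (any residual
#' below `2 rr_max` can be closed by two in-bounds intervals once the
#' deviation budget is wide enough).
#'
#' @param series An `rr_series` containing the gap.
#' @param gap One row of [detect_gaps()] output.
#' @param params Output of [fit_local_gaussian()] (a list with `mu`, `sigma`).
#' @param bounds A [physio_bounds()] object.
#' @param rng_seed Integer seed; the same seed always produces the same fill.
#'   The global RNG state is left untouched.
#' @param cap Initial deviation budget; defaults to the pre-gap
#'   [local_mean_deviation()] (frozen per gap — recomputing it from
#'   self-generated data would be circular).
#' @return A list: `series` (the series with the gap filled), `log` (one-row
#'   tibble: `n_inserted`, `attempts`, `cap_final`, `forced` — `forced` marks
#'   the degenerate case of a residual smaller than `rr_min`, which no
#'   in-bounds tiling can close).
#' @export
fill_gap <- function(series, gap, params = fit_local_gaussian(series, gap, bounds),
                     bounds = physio_bounds(), rng_seed = 1L, cap = NULL) {
  series <- as_rr_series(series)
  tol <- 1e-9
  if (is.null(cap)) {
    pre <- series$rr[series$time <= gap$t_start + tol]
    cap <- if (length(pre) >= 3) {
      local_dev_rr(pre, length(pre) + 1L, bounds)
    } else {
      bounds$max_deviation
    }
  }
  fill <- fill_gap_core(gap$t_start, gap$t_end, gap$rr_end,
                        rr_start = {
                          pre <- series$rr[series$time <= gap$t_start + tol]
                          if (length(pre)) tail(pre, 1L) else NA_real_
                        },
                        params = params, bounds = bounds, seed = rng_seed,
                        cap = cap)
  df <- dplyr::arrange(
    dplyr::bind_rows(series[, c("time", "rr")],
                     tibble::tibble(time = fill$time, rr = fill$rr)),
    .data$time)
  out <- new_rr_series(df, label = rr_label(series))
  list(series = out, log = fill$log)
}

# backward filling of a single gap; returns inserted beats (increasing time)
fill_gap_core <- function(t_start, t_end, rr_end, rr_start, params, bounds,
                          seed, cap, max_iter = 1e6) {
  withr::with_seed(seed, {
    mu <- params$mu
    sigma <- params$sigma
    sigma_work <- sigma
    cap_now <- cap
    ins_t <- numeric(0) # decreasing time order
    ins_rr <- numeric(0)
    attempts <- 0L
    forced <- FALSE
    iter <- 0L
    tol <- 1e-9

    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("gap filling failed to terminate", call. = FALSE)
      k <- length(ins_t)
      next_pos <- if (k == 0L) t_end - rr_end else ins_t[k] - ins_rr[k]
      resid <- next_pos - t_start
      succ <- if (k == 0L) rr_end else ins_rr[k]

      if (resid < bounds$rr_max) {
        # deterministic closing interval (residual span to t_start)
        v <- resid
        dev_s <- abs(succ - v) / v
        dev_p <- if (is.na(rr_start)) 0 else abs(v - rr_start) / rr_start
        ok <- v >= bounds$rr_min - tol && v <= bounds$rr_max + tol &&
          dev_s <= cap_now + tol && dev_p <= cap_now + tol
        if (ok) {
          ins_t <- c(ins_t, next_pos)
          ins_rr <- c(ins_rr, v)
          break
        }
        if (k == 0L) {
          # nothing to regenerate: the residual is fixed, so an in-bounds
          # value failing only the deviation budget is what cap escalation
          # would eventually accept anyway; a residual outside the bounds is
          # genuinely unclosable and gets flagged
          ins_t <- c(ins_t, next_pos)
          ins_rr <- c(ins_rr, v)
          forced <- v < bounds$rr_min - tol || v > bounds$rr_max + tol
          break
        }
        attempts <- attempts + 1L
        if (attempts %% 4L == 0L) cap_now <- cap_now + 0.05
        if (sigma_work < 0.01) sigma_work <- 0.01 # deterministic sampler cannot move
        drop <- seq.int(max(1L, k - 1L), k)
        ins_t <- ins_t[-drop]
        ins_rr <- ins_rr[-drop]
        next
      }

      # sample a beat at next_pos
      v <- NA_real_
      for (try in seq_len(1000L)) {
        cand <- rnorm(1L, mu, sigma_work)
        if (cand >= bounds$rr_min && cand <= bounds$rr_max &&
            abs(succ - cand) / cand <= cap_now + tol) {
          v <- cand
          break
        }
      }
      if (is.na(v)) {
        lo <- max(bounds$rr_min, mu - 2 * sigma_work)
        hi <- min(bounds$rr_max, mu + 2 * sigma_work)
        if (lo > hi) { lo <- bounds$rr_min; hi <- bounds$rr_max }
        v <- min(max(cand, lo), hi)
      }
      ins_t <- c(ins_t, next_pos)
      ins_rr <- c(ins_rr, v)
    }

    ord <- order(ins_t)
    list(time = ins_t[ord], rr = ins_rr[ord],
         log = tibble::tibble(n_inserted = length(ins_t),
                              attempts = attempts, cap_final = cap_now,
                              forced = forced))
  })
}

#' Impute all gaps of a filtered series (the DVC method)
#'
#' Detects every gap, fits each one's local Gaussian from the original
#' (pre-fill) data, and fills them with [fill_gap()]; each gap consumes an
#' independent sub-seed (`rng_seed + gap ordinal`) so fills are
#' order-insensitive and reproducible. Adjacencies whose timestamp difference
#' is at most `rr_max` but disagrees with the recorded interval (a lost beat
#' whose span still fits inside one or two physiological intervals, so it is
#' not a gap by the `rr_max` criterion) are repaired with the same machinery:
#' when the residual span beyond the recorded interval can hold a
#' physiological beat it is filled backwards like a miniature gap — which
#' restores a single deleted beat exactly, since the interval recorded after
#' it is true data — and otherwise the interval is reset to the timestamp
#' difference, the timestamps being the trusted observable. The output is
#' fully consistent with all intervals inside the physiological bounds.
#'
#' @param series An `rr_series`, normally the output of [filter_ectopics()].
#' @param bounds A [physio_bounds()] object.
#' @param rng_seed Integer seed.
#' @return The imputed series (class `rr_imputed`) with a per-gap fill log
#'   attached; retrieve it with [tidy()] or [fill_log()]. [glance()] gives a
#'   one-row summary.
#' @examples
#' s <- rr_series(time = c(cumsum(rep(0.8, 10)), 8 + 4.2), rr = c(rep(0.8, 10), 0.8))
#' imp <- impute_dvc(s, rng_seed = 42)
#' check_consistency(imp)
#' @export
impute_dvc <- function(series, bounds = physio_bounds(), rng_seed = 1L) {
  series <- as_rr_series(series)
  time <- series$time
  rr <- series$rr
  tol <- 1e-9

  # mismatch adjacencies (dT <= rr_max but != recorded interval): fill like a
  # miniature gap when the residual can hold a beat, reset to dT otherwise
  reset <- integer(0)
  jobs <- NULL
  if (length(rr) >= 2) {
    dt <- diff(time)
    mism <- which(abs(rr[-1] - dt) > tol & dt <= bounds$rr_max + tol) + 1L
    fillable <- mism[dt[mism - 1L] - rr[mism] >= bounds$rr_min - tol]
    reset <- setdiff(mism, fillable)
    rr[reset] <- dt[reset - 1L]
    if (length(fillable)) {
      jobs <- tibble::tibble(t_start = time[fillable - 1L],
                             t_end = time[fillable],
                             rr_end = rr[fillable],
                             span = dt[fillable - 1L],
                             kind = "mismatch")
    }
  }
  base <- new_rr_series(tibble::tibble(time = time, rr = rr),
                        label = rr_label(series))

  gaps <- detect_gaps(base, bounds, tol)
  jobs <- dplyr::arrange(
    dplyr::bind_rows(jobs,
                     dplyr::mutate(gaps[, c("t_start", "t_end", "rr_end",
                                            "span")],
                                   kind = "gap")),
    .data$t_start)
  logs <- vector("list", nrow(jobs))
  pieces <- list(base[, c("time", "rr")])
  for (g in seq_len(nrow(jobs))) {
    gap <- jobs[g, ]
    params <- fit_local_gaussian(base, gap, bounds)
    pre <- base$rr[base$time <= gap$t_start + tol]
    cap <- if (length(pre) >= 3) local_dev_rr(pre, length(pre) + 1L, bounds)
           else bounds$max_deviation
    fill <- fill_gap_core(gap$t_start, gap$t_end, gap$rr_end,
                          rr_start = if (length(pre)) tail(pre, 1L) else NA_real_,
                          params = params, bounds = bounds,
                          seed = rng_seed + g, cap = cap)
    pieces[[g + 1L]] <- tibble::tibble(time = fill$time, rr = fill$rr)
    logs[[g]] <- dplyr::bind_cols(
      tibble::tibble(gap = g), jobs[g, c("t_start", "t_end", "span", "kind")],
      fill$log)
  }
  df <- dplyr::arrange(dplyr::bind_rows(pieces), .data$time)
  out <- new_rr_series(df, label = rr_label(series), subclass = "rr_imputed")
  attr(out, "fill_log") <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(gap = integer(0), t_start = numeric(0), t_end = numeric(0),
                   span = numeric(0), kind = character(0),
                   n_inserted = integer(0), attempts = integer(0),
                   cap_final = numeric(0), forced = logical(0))
  attr(out, "repaired") <- reset
  out
}

#' Per-gap fill log of an imputation run
#' @param x The result of [impute_dvc()].
#' @return A tibble with one row per filled gap.
#' @export
fill_log <- function(x) {
  attr(x, "fill_log") %||%
    stop("no fill log attached; run impute_dvc() first", call. = FALSE)
}

#' @method tidy rr_imputed
#' @export
tidy.rr_imputed <- function(x, ...) fill_log(x)

#' @method glance rr_imputed
#' @export
glance.rr_imputed <- function(x, ...) {
  lg <- fill_log(x)
  tibble::tibble(n_beats = nrow(x), n_gaps = nrow(lg),
                 n_inserted = sum(lg$n_inserted),
                 n_repaired = length(attr(x, "repaired") %||% integer(0)),
                 max_cap = if (nrow(lg)) max(lg$cap_final) else NA_real_,
                 any_forced = any(lg$forced))
}
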
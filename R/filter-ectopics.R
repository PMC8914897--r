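#' Local variability budget for beat repair
#'
#' The mean absolute successive relative difference of the intervals
#' immediately preceding a beat, capped at `bounds$max_deviation`. This is the
#' budget against which the deviation of a merged or inserted interval from
#' its neighbours is judged: a repair is physiologically acceptable when it
#' deviates from its neighbours by no more than the signal already varied just
#' before. With fewer than `bounds$lookback` preceding interval pairs the mean
#' runs over however many exist; with none at all (the first two beats) the
#' cap itself is returned.
#'
#' @param series An `rr_series` (or anything [as_rr_series()] accepts).
#' @param index Beat position (1-based) under repair; must be >= 2.
#' @param bounds A [physio_bounds()] object.
#' @return A single non-negative fraction, at most `bounds$max_deviation`.
#' @examples
#' s <- rr_series(time = cumsum(rep(0.8, 12)))
#' local_mean_deviation(s, 12) # constant series: 0
#' @export
local_mean_deviation <- function(series, index, bounds = physio_bounds()) {
  series <- as_rr_series(series)
  stopifnot(index >= 2, index <= nrow(series))
  local_dev_rr(series$rr, index, bounds)
}

# successive relative differences |rr[k] - rr[k-1]| / rr[k-1] for the
# `lookback` pairs immediately before position i, capped
local_dev_rr <- function(rr, i, bounds) {
  ks <- seq.int(max(2L, i - bounds$lookback), i - 1L)
  ks <- ks[ks >= 2L & ks <= i - 1L]
  if (i < 3L || !length(ks)) return(bounds$max_deviation)
  raw <- mean(abs(rr[ks] - rr[ks - 1L]) / rr[ks - 1L])
  min(raw, bounds$max_deviation)
}

#' Evaluate a right or left merge candidate for a short interval
#'
#' A sub-`rr_min` interval is presumed to be a spurious extra peak detection
#' splitting one true interval in two; the repair absorbs it into a
#' neighbour. A *right* merge adds the short interval to its successor and
#' places the merged value at the successor's timestamp; a *left* merge adds
#' it to its predecessor and places the merged value at the short beat's own
#' timestamp. Either way the spanned time is conserved exactly, so the
#' timestamp-interval equality survives. The candidate's deviations are
#' measured against the post-merge successor (relative to the merged value)
#' and the post-merge predecessor (relative to that predecessor); at a series
#' edge the missing comparison is treated as satisfied and reported as `NA`.
#'
#' @param series An `rr_series`.
#' @param index Position of the short interval.
#' @param kind `"right"` or `"left"`.
#' @param bounds A [physio_bounds()] object.
#' @return A one-row tibble: `kind`, `merged_value` (s), `err_succ`,
#'   `err_pred` (fractions, `NA` when the neighbour is missing), `err_total`
#'   (missing terms count as zero).
#' @examples
#' s <- rr_series(time = c(0.8, 1.0, 1.7), rr = c(0.8, 0.2, 0.7))
#' evaluate_merge(s, 2, "right")
#' evaluate_merge(s, 2, "left")
#' @export
evaluate_merge <- function(series, index, kind = c("right", "left"),
                           bounds = physio_bounds()) {
  kind <- match.arg(kind)
  series <- as_rr_series(series)
  rr <- series$rr
  n <- length(rr)
  if (rr[index] >= bounds$rr_min) {
    stop("evaluate_merge() expects an interval below rr_min at `index`",
         call. = FALSE)
  }
  nb <- if (kind == "right") index + 1L else index - 1L
  if (nb < 1L || nb > n) {
    stop(sprintf("no %s neighbour at index %d", kind, index), call. = FALSE)
  }
  merged <- rr[index] + rr[nb]
  if (kind == "right") {
    succ <- if (index + 2L <= n) rr[index + 2L] else NA_real_
    pred <- if (index - 1L >= 1L) rr[index - 1L] else NA_real_
  } else {
    succ <- if (index + 1L <= n) rr[index + 1L] else NA_real_
    pred <- if (index - 2L >= 1L) rr[index - 2L] else NA_real_
  }
  err_succ <- abs(succ - merged) / merged
  err_pred <- abs(merged - pred) / pred
  tibble::tibble(kind = kind, merged_value = merged,
                 err_succ = err_succ, err_pred = err_pred,
                 err_total = sum(err_succ, err_pred, na.rm = TRUE))
}

#' Remove ectopic intervals by deletion and physiologically validated merges
#'
#' One-pass-at-a-time, left-to-right repair of all out-of-bounds intervals.
#' Intervals above `rr_max` are deleted together with their timestamps
#' (missed beats; the resulting gaps are handed to [impute_dvc()]). Each
#' interval below `rr_min` is resolved in branch order: a right merge is
#' applied if the merged value lies strictly inside the bounds and both its
#' deviations fit within the local budget ([local_mean_deviation()]); failing
#' that, a left merge under the same conditions; failing both, if both merged
#' values exceed `rr_max` the short beat and its successor are deleted; if
#' exactly one merged value is within `rr_max` that merge is forced through
#' even though its deviations exceed the budget (the bounds condition alone
#' guarantees convergence); and if both merged values are within `rr_max` but
#' both fail the deviation budget, the merge with the smaller total error
#' wins (ties go right, matching the try-right-first order).
#'
#' A merge partner must be a physiological interval whose adjacency with the
#' short beat is itself consistent — a neighbour across a gap or a timestamp
#' mismatch is treated as missing, as is a neighbour outside the bounds. A
#' short beat with no usable partner on either side is deleted. A merge's
#' output value is only re-examined on a subsequent full pass; passes repeat
#' until nothing changes (at most five).
#'
#' @param series An `rr_series`.
#' @param bounds A [physio_bounds()] object.
#' @param tol Consistency tolerance in seconds.
#' @return The filtered series (class `rr_filtered`, still an `rr_series`
#'   tibble) with the audit trail attached; retrieve it with [tidy()] or
#'   [filter_report()]. Every action row records the pass, the beat position
#'   and timestamp at action time, the action taken, and the interval before
#'   and after (`NA` after a deletion).
#' @examples
#' s <- rr_series(time = c(0.8, 1.0, 1.7), rr = c(0.8, 0.2, 0.7))
#' f <- filter_ectopics(s)
#' f
#' tidy(f)
#' @export
filter_ectopics <- function(series, bounds = physio_bounds(), tol = 1e-9) {
  series <- as_rr_series(series)
  res <- filter_core(series$time, series$rr, bounds, tol)
  out <- new_rr_series(tibble::tibble(time = res$time, rr = res$rr),
                       label = rr_label(series), subclass = "rr_filtered")
  attr(out, "report") <- res$report
  attr(out, "bounds") <- bounds
  out
}

#' Audit trail of a filtering run
#' @param x The result of [filter_ectopics()].
#' @return A tibble with one row per merge/deletion decision.
#' @export
filter_report <- function(x) {
  attr(x, "report") %||%
    stop("no filter report attached; run filter_ectopics() first", call. = FALSE)
}

#' @method tidy rr_filtered
#' @export
tidy.rr_filtered <- function(x, ...) filter_report(x)

#' @method glance rr_filtered
#' @export
glance.rr_filtered <- function(x, ...) {
  rep <- filter_report(x)
  tibble::tibble(
    n_beats = nrow(x),
    n_actions = nrow(rep),
    n_deleted_long = sum(rep$action == "delete_long"),
    n_merged = sum(rep$action %in% c("right_merge", "left_merge",
                                     "forced_right", "forced_left",
                                     "least_error_merge")),
    n_deleted_short = sum(rep$action %in% c("delete_pair", "delete_unmergeable")),
    n_passes = if (nrow(rep)) max(rep$pass) else 0L
  )
}

# vectorised work-horse; operates on bare time/rr vectors and returns them
# plus the action log. Kept tibble-free because the exhaustive small-series
# corpora run it tens of thousands of times.
filter_core <- function(time, rr, bounds, tol = 1e-9, max_passes = 5L) {
  acts <- list()
  add <- function(pass, i, action, before, after) {
    acts[[length(acts) + 1L]] <<- list(pass = pass, index = i, time = time[i],
                                       action = action, before = before,
                                       after = after)
  }
  rmv <- function(idx) {
    time <<- time[-idx]
    rr <<- rr[-idx]
  }
  consistent_adj <- function(j) { # adjacency (j-1, j)
    j >= 2L && abs(time[j] - time[j - 1L] - rr[j]) <= tol
  }

  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    i <- 1L
    while (i <= length(rr)) {
      n <- length(rr)
      if (rr[i] > bounds$rr_max) {
        add(pass, i, "delete_long", rr[i], NA_real_)
        rmv(i)
        changed <- TRUE
        next
      }
      if (rr[i] >= bounds$rr_min) {
        i <- i + 1L
        next
      }
      # --- short interval: resolve by merge/deletion ------------------------
      changed <- TRUE
      in_phys <- function(v) v >= bounds$rr_min && v <= bounds$rr_max
      r_ok <- i < n && consistent_adj(i + 1L) && in_phys(rr[i + 1L])
      l_ok <- i > 1L && consistent_adj(i) && in_phys(rr[i - 1L])
      e10 <- local_dev_rr(rr, i, bounds)
      ok_dev <- function(e) is.na(e) || e <= e10

      rr_r <- if (r_ok) rr[i] + rr[i + 1L] else NA_real_
      rr_l <- if (l_ok) rr[i] + rr[i - 1L] else NA_real_
      er_s <- if (r_ok && i + 2L <= n) abs(rr[i + 2L] - rr_r) / rr_r else NA_real_
      er_p <- if (r_ok && i >= 2L) abs(rr_r - rr[i - 1L]) / rr[i - 1L] else NA_real_
      el_s <- if (l_ok && i + 1L <= n) abs(rr[i + 1L] - rr_l) / rr_l else NA_real_
      el_p <- if (l_ok && i >= 3L) abs(rr_l - rr[i - 2L]) / rr[i - 2L] else NA_real_

      do_right <- function(action) {
        add(pass, i, action, rr[i], rr_r)
        rr[i + 1L] <<- rr_r
        rmv(i)
        i <<- i + 1L # merged value sits at position i; re-examined next pass
      }
      do_left <- function(action) {
        add(pass, i, action, rr[i], rr_l)
        rr[i] <<- rr_l
        rmv(i - 1L)
        # merged value now at i-1; continue with the old successor at i
      }

      strict_in <- function(v) v > bounds$rr_min && v < bounds$rr_max
      if (r_ok && strict_in(rr_r) && ok_dev(er_s) && ok_dev(er_p)) {
        do_right("right_merge")
      } else if (l_ok && strict_in(rr_l) && ok_dev(el_s) && ok_dev(el_p)) {
        do_left("left_merge")
      } else if (r_ok && l_ok) {
        ok40 <- function(a, b) {
          (is.na(a) || a <= bounds$max_deviation) &&
            (is.na(b) || b <= bounds$max_deviation)
        }
        if (rr_r > bounds$rr_max && rr_l > bounds$rr_max) {
          add(pass, i, "delete_pair", rr[i], NA_real_)
          rmv(c(i, i + 1L))
        } else if (rr_r <= bounds$rr_max && rr_l > bounds$rr_max) {
          do_right("forced_right")
        } else if (rr_l <= bounds$rr_max && rr_r > bounds$rr_max) {
          do_left("forced_left")
        } else if (ok40(er_s, er_p)) {
          # deviations above the local budget but within the 40% ceiling:
          # conditions two and three are dropped for convergence, in
          # try-right-first order
          do_right("forced_right")
        } else if (ok40(el_s, el_p)) {
          do_left("forced_left")
        } else {
          # deviations above 40% on both sides: smallest total error wins
          et_r <- sum(er_s, er_p, na.rm = TRUE)
          et_l <- sum(el_s, el_p, na.rm = TRUE)
          if (et_r <= et_l) do_right("least_error_merge")
          else do_left("least_error_merge")
        }
      } else if (r_ok) {
        if (rr_r <= bounds$rr_max) {
          do_right("forced_right")
        } else {
          add(pass, i, "delete_pair", rr[i], NA_real_)
          rmv(c(i, i + 1L))
        }
      } else if (l_ok) {
        if (rr_l <= bounds$rr_max) {
          do_left("forced_left")
        } else {
          add(pass, i, "delete_unmergeable", rr[i], NA_real_)
          rmv(i)
        }
      } else {
        add(pass, i, "delete_unmergeable", rr[i], NA_real_)
        rmv(i)
      }
    }
    if (!changed) break
  }

  report <- tibble::new_tibble(list(
    pass = vapply(acts, `[[`, integer(1), "pass"),
    index = vapply(acts, `[[`, integer(1), "index"),
    time = vapply(acts, `[[`, numeric(1), "time"),
    action = vapply(acts, `[[`, character(1), "action"),
    before = vapply(acts, `[[`, numeric(1), "before"),
    after = vapply(acts, `[[`, numeric(1), "after")
  ), nrow = length(acts))
  list(time = time, rr = rr, report = report)
}
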
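#' Simulate a realistic RR-interval series
#'
#' Beats are laid down sequentially so the series is fully consistent by
#' construction: each interval is the instantaneous modulation signal
#' `mean_rr + lf_amp sin(2 pi lf_hz t) + hf_amp sin(2 pi hf_hz t)` sampled at
#' the current beat time, plus white Gaussian jitter whose standard deviation
#' is chosen so the overall SDNN hits `sdnn_target` (a sinusoid of amplitude
#' `a` contributes `a^2 / 2` to the variance). The two sinusoids emulate the
#' sympathetic (LF, ~0.1 Hz) and respiratory/vagal (HF, ~0.25 Hz) rhythms
#' that dominate short-term heart-rate variability.
#'
#' A slow drift term (`drift_amp`, `drift_period_s`, random phase) moves the
#' local mean over minutes, emulating the within-recording nonstationarity of
#' real ambulatory data (posture shifts, slow autonomic trends); with
#' `drift_amp = 0` the series is stationary.
#'
#' @param duration_s Recording length in seconds.
#' @param mean_rr Mean interval in seconds (must leave room inside the
#'   physiological bounds for the modulation).
#' @param sdnn_target Target overall SDNN in seconds, excluding the drift
#'   term.
#' @param lf_amp,hf_amp Sinusoid amplitudes in seconds.
#' @param lf_hz,hf_hz Sinusoid frequencies in Hz.
#' @param drift_amp Amplitude of the slow mean drift in seconds (default 0).
#' @param drift_period_s Period of the drift in seconds.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param label Optional condition tag.
#' @param bounds A [physio_bounds()] object; the deterministic envelope
#'   `mean_rr +/- (lf_amp + hf_amp + 4 jitter_sd)` must fit inside it, else
#'   an error is raised. The rare jitter draw beyond 4 sd is clamped.
#' @return A fully consistent `rr_series`.
#' @examples
#' s <- simulate_rr(duration_s = 600, seed = 1)
#' sdnn(s$rr)
#' @export
simulate_rr <- function(duration_s, mean_rr = 0.8, sdnn_target = 0.05,
                        lf_amp = 0.02, hf_amp = 0.03,
                        lf_hz = 0.1, hf_hz = 0.25,
                        drift_amp = 0, drift_period_s = 480,
                        seed = 1L, label = NULL,
                        bounds = physio_bounds()) {
  stopifnot(mean_rr > bounds$rr_min, mean_rr < bounds$rr_max, duration_s > 0)
  jitter_var <- sdnn_target^2 - lf_amp^2 / 2 - hf_amp^2 / 2
  if (jitter_var < 0) {
    stop("sdnn_target smaller than the variability already carried by the sinusoids",
         call. = FALSE)
  }
  jitter_sd <- sqrt(jitter_var)
  env <- lf_amp + hf_amp + drift_amp + 4 * jitter_sd
  if (mean_rr - env < bounds$rr_min || mean_rr + env > bounds$rr_max) {
    stop(sprintf(
      "parameters force beats outside [%g, %g] s (envelope %.3f +/- %.3f)",
      bounds$rr_min, bounds$rr_max, mean_rr, env), call. = FALSE)
  }
  withr::with_seed(seed, {
    n_max <- ceiling(duration_s / (mean_rr - env)) + 1L
    noise <- pmin(pmax(rnorm(n_max, 0, jitter_sd), -4 * jitter_sd),
                  4 * jitter_sd)
    drift_phase <- runif(1, 0, 2 * pi)
    t <- numeric(n_max)
    rr <- numeric(n_max)
    now <- 0
    k <- 0L
    while (TRUE) {
      v <- mean_rr + lf_amp * sin(2 * pi * lf_hz * now) +
        hf_amp * sin(2 * pi * hf_hz * now) +
        drift_amp * sin(2 * pi * now / drift_period_s + drift_phase) +
        noise[k + 1L]
      now <- now + v
      if (now > duration_s) break
      k <- k + 1L
      t[k] <- now
      rr[k] <- v
    }
    rr_series(time = t[seq_len(k)], rr = rr[seq_len(k)], label = label)
  })
}

#' Condition presets for the stress-classification experiments
#'
#' `"relax"` has a longer mean interval and stronger respiratory (HF)
#' modulation; `"stress"` a shorter mean interval, stronger LF modulation and
#' damped HF — the canonical autonomic signatures the downstream classifier
#' is meant to separate.
#'
#' @param preset `"relax"` or `"stress"`.
#' @param duration_s Recording length in seconds (default 900 s relaxed,
#'   1200 s stressed).
#' @param seed Integer seed.
#' @return A labelled `rr_series`.
#' @export
simulate_preset <- function(preset = c("relax", "stress"), duration_s = NULL,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "relax") {
    simulate_rr(duration_s %||% 900, mean_rr = 0.9, sdnn_target = 0.05,
                lf_amp = 0.02, hf_amp = 0.04, seed = seed, label = "relax")
  } else {
    simulate_rr(duration_s %||% 1200, mean_rr = 0.7, sdnn_target = 0.045,
                lf_amp = 0.04, hf_amp = 0.012, seed = seed, label = "stress")
  }
}

#' Simulate a labelled two-condition corpus
#'
#' Emulates a multi-subject study: every series draws its own physiology from
#' per-condition ranges (uniformly, seeded), so the classes form realistic
#' overlapping clouds rather than two points. Relaxed subjects: mean RR
#' 0.85-0.98 s, stronger respiratory (HF) modulation; stressed subjects: mean
#' RR 0.62-0.78 s, stronger LF modulation, damped HF. Overall SDNN is drawn
#' from 35-55 ms for both.
#'
#' @param n_per_class Series per condition.
#' @param duration_s Length of every series in seconds.
#' @param seed Integer seed; each series uses a derived sub-seed.
#' @return A list of labelled `rr_series`.
#' @export
simulate_corpus <- function(n_per_class = 10L, duration_s = 600, seed = 1L) {
  draw <- function(i, label) {
    withr::with_seed(seed * 1000L + i + 500L * (label == "stress"), {
      p <- if (label == "relax") {
        list(mean_rr = runif(1, 0.70, 0.98), lf = runif(1, 0.012, 0.035),
             hf = runif(1, 0.012, 0.045))
      } else {
        list(mean_rr = runif(1, 0.62, 0.92), lf = runif(1, 0.018, 0.045),
             hf = runif(1, 0.008, 0.032))
      }
      # draw the white-jitter level and derive the implied overall SDNN so
      # any sinusoid draw stays feasible
      p$sdnn <- sqrt(runif(1, 0.025, 0.045)^2 + p$lf^2 / 2 + p$hf^2 / 2)
      p$drift <- runif(1, 0.02, 0.06)
      p$drift_period <- runif(1, 240, 600)
      p
    })
  }
  gen <- function(i, label) {
    p <- draw(i, label)
    simulate_rr(duration_s, mean_rr = p$mean_rr, sdnn_target = p$sdnn,
                lf_amp = p$lf, hf_amp = p$hf,
                drift_amp = p$drift, drift_period_s = p$drift_period,
                seed = seed * 1000L + i + 500L * (label == "stress"),
                label = label)
  }
  c(purrr::map(seq_len(n_per_class), gen, label = "relax"),
    purrr::map(seq_len(n_per_class), gen, label = "stress"))
}

#' Degrade an RR series: random beat deletion plus ectopic injection
#'
#' Emulates ambulatory signal loss and false peak detections with ground
#' truth retained. `round(missing_pct / 100 * n)` beats are deleted
#' (timestamp and interval removed, so surviving timestamps are untouched and
#' gaps open up). A disjoint set of `round(ectopic_pct / 100 * n)` beats has
#' its interval replaced by an ectopic pair: a spurious extra peak is placed
#' at the predecessor timestamp plus a uniform draw from 0.1 s up to
#' `rr_min`, carrying that sub-physiological interval, and the true beat's
#' interval shrinks to the remainder — exactly the false-detection mechanism
#' the merge filter is designed to undo (a right merge of the ectopic
#' restores the original interval). Both adjacencies stay consistent, each
#' injection leaves exactly one sub-`rr_min` interval, and only beats long
#' enough for a physiological remainder (>= `rr_min` + 0.15 s) are eligible.
#' Deletions are beat-wise uniform by default, which produces
#' geometric-length gap runs; `burst = TRUE` deletes contiguous runs instead,
#' emulating bursty sensor dropouts.
#'
#' @param series An `rr_series`.
#' @param missing_pct,ectopic_pct Percentages of the beat count in `[0, 50)`.
#' @param seed Integer seed.
#' @param burst Delete contiguous runs instead of independent beats.
#' @param bounds A [physio_bounds()] object.
#' @return The degraded series (class `rr_degraded`) with the plan attached;
#'   retrieve it with [degradation_plan()]. The plan records the deleted rows
#'   and the injected ectopics with their original values, so the deletion
#'   part is exactly invertible via [restore_deletions()].
#' @examples
#' s <- simulate_rr(600, seed = 1)
#' d <- degrade(s, missing_pct = 20, ectopic_pct = 5, seed = 2)
#' degradation_plan(d)$deleted
#' @export
degrade <- function(series, missing_pct, ectopic_pct = 0, seed = 1L,
                    burst = FALSE, bounds = physio_bounds()) {
  series <- as_rr_series(series)
  stopifnot(missing_pct >= 0, missing_pct < 50,
            ectopic_pct >= 0, ectopic_pct < 50)
  n <- nrow(series)
  n_del <- round(missing_pct / 100 * n)
  n_ect <- round(ectopic_pct / 100 * n)
  if (n_del + n_ect > n) stop("requested fractions exceed available beats",
                              call. = FALSE)
  withr::with_seed(seed, {
    splittable <- which(series$rr >= bounds$rr_min + 0.15)
    if (length(splittable) < n_ect) {
      stop("not enough beats long enough to host an ectopic injection",
           call. = FALSE)
    }
    ect_idx <- sort(sample(splittable, n_ect))
    pool <- setdiff(seq_len(n), ect_idx)
    del_idx <- if (burst && n_del > 0) {
      picked <- integer(0)
      while (length(picked) < n_del) {
        run <- min(1L + stats::rgeom(1L, 1 / 3), n_del - length(picked))
        start <- sample(pool, 1L)
        take <- intersect(seq.int(start, min(start + run - 1L, n)), pool)
        picked <- union(picked, take)
        pool <- setdiff(pool, take)
      }
      sort(picked)
    } else {
      sort(sample(pool, n_del))
    }

    time <- series$time
    rr <- series$rr
    # spurious extra peak splits interval i: ectopic draw capped so the
    # remainder stays a physiological interval
    hi <- pmin(bounds$rr_min, rr[ect_idx] - bounds$rr_min)
    rr_new <- runif(n_ect, 0.1, hi)
    ect_rows <- tibble::tibble(index = ect_idx, time_orig = time[ect_idx],
                               rr_orig = rr[ect_idx], rr_new = rr_new,
                               time_new = NA_real_)
    extra_t <- numeric(n_ect)
    for (j in seq_along(ect_idx)) {
      i <- ect_idx[j]
      prev_t <- if (i > 1L) time[i - 1L] else time[i] - rr[i]
      extra_t[j] <- prev_t + rr_new[j]
      rr[i] <- rr[i] - rr_new[j]
      ect_rows$time_new[j] <- extra_t[j]
    }
    del_rows <- tibble::tibble(index = del_idx, time = series$time[del_idx],
                               rr = series$rr[del_idx])
    keep <- setdiff(seq_len(n), del_idx)
    df <- dplyr::arrange(
      dplyr::bind_rows(tibble::tibble(time = time[keep], rr = rr[keep]),
                       tibble::tibble(time = extra_t, rr = rr_new)),
      .data$time)
    if (nrow(df) > 1) {
      df <- df[c(TRUE, diff(df$time) > 0), ] # drop pathological timestamp clashes
    }
    out <- new_rr_series(df, label = rr_label(series), subclass = "rr_degraded")
    attr(out, "plan") <- structure(
      list(missing_pct = missing_pct, ectopic_pct = ectopic_pct, seed = seed,
           deleted_indices = del_idx, ectopic_indices = ect_idx,
           deleted = del_rows, ectopic = ect_rows),
      class = "degradation_plan")
    out
  })
}

#' Ground-truth plan of a degradation run
#' @param x The result of [degrade()].
#' @return A `degradation_plan` list.
#' @export
degradation_plan <- function(x) {
  attr(x, "plan") %||%
    stop("no degradation plan attached; run degrade() first", call. = FALSE)
}

#' @export
print.degradation_plan <- function(x, ...) {
  cat(sprintf("degradation plan: %d beats deleted (%g%%), %d ectopics injected (%g%%), seed %d\n",
              length(x$deleted_indices), x$missing_pct,
              length(x$ectopic_indices), x$ectopic_pct, x$seed))
  invisible(x)
}

#' Undo the deletion part of a degradation
#'
#' Re-inserts the deleted rows recorded in the plan. With no ectopic
#' injection this restores the original series exactly.
#'
#' @param degraded The result of [degrade()].
#' @param plan The matching [degradation_plan()]; defaults to the attached one.
#' @return An `rr_series`.
#' @export
restore_deletions <- function(degraded, plan = degradation_plan(degraded)) {
  df <- dplyr::arrange(
    dplyr::bind_rows(tibble::as_tibble(degraded)[, c("time", "rr")],
                     plan$deleted[, c("time", "rr")]),
    .data$time)
  new_rr_series(df, label = rr_label(degraded), validate = TRUE)
}
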
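#' Time-domain HRV features
#'
#' `sdnn()` is the sample standard deviation of the intervals (n-1
#' denominator); `rmssd()` the root mean square of successive differences
#' (mean over the N-1 difference terms); `pnn50()` counts successive pairs
#' differing by more than 50 ms (`nn50`) and expresses them as a percentage
#' of the N-1 pairs. All take intervals in seconds and report milliseconds
#' (counts and percentages for `pnn50`). With fewer than two intervals the
#' feature is undefined and `NA` is returned.
#'
#' @param intervals Numeric vector of RR intervals in seconds.
#' @return `sdnn()`, `rmssd()`: a scalar in ms. `pnn50()`: a named list with
#'   `nn50` (count) and `pnn50` (percent).
#' @examples
#' sdnn(c(0.7, 0.9)) # 141.42 ms
#' rmssd(c(0.8, 0.9, 0.8)) # 100 ms
#' pnn50(c(0.8, 0.9, 0.8)) # both pairs exceed 50 ms
#' @export
sdnn <- function(intervals) {
  if (length(intervals) < 2) return(NA_real_)
  sd(intervals) * 1000
}

#' @rdname sdnn
#' @export
rmssd <- function(intervals) {
  if (length(intervals) < 2) return(NA_real_)
  sqrt(mean(diff(intervals)^2)) * 1000
}

#' @rdname sdnn
#' @export
pnn50 <- function(intervals) {
  if (length(intervals) < 2) return(list(nn50 = NA_integer_, pnn50 = NA_real_))
  d <- abs(diff(intervals))
  nn50 <- sum(d > 0.05)
  list(nn50 = as.integer(nn50), pnn50 = 100 * nn50 / (length(intervals) - 1))
}

#' Poincare-plot axes SD1 and SD2
#'
#' The Poincare plot scatters each interval against its successor; an ellipse
#' fitted to the cloud has its minor axis perpendicular to the identity line
#' (beat-to-beat scatter, short-term variability) and its major axis along it
#' (longer-term variability). The standard rotation identities give the axis
#' standard deviations directly: `SD1^2 = Var(diff(RR)) / 2` and
#' `SD2^2 = 2 Var(RR) - Var(diff(RR)) / 2`, so `SD1^2 + SD2^2 = 2 Var(RR)`
#' always. A negative SD2 radicand (numerically possible for strongly
#' alternating series) is clamped to zero.
#'
#' @param intervals Numeric vector of RR intervals in seconds (at least 3).
#' @return A named list with `sd1` and `sd2` in ms.
#' @examples
#' poincare_sd(c(0.8, 0.85, 0.78, 0.82, 0.8))
#' @export
poincare_sd <- function(intervals) {
  if (length(intervals) < 3) return(list(sd1 = NA_real_, sd2 = NA_real_))
  vd <- var(diff(intervals))
  v <- var(intervals)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(0, 2 * v - vd / 2))
  list(sd1 = sd1 * 1000, sd2 = sd2 * 1000)
}

#' Spectral HRV powers in the LF and HF bands
#'
#' The tachogram (interval versus timestamp) is interpolated onto a uniform
#' grid (cubic interpolation, default 8 Hz), mean-detrended, and its power
#' spectral density estimated by a Welch periodogram (Hann windows of up to
#' 2 min, 50% overlap; shorter signals use a single segment). LF is the
#' integrated density over 0.04-0.15 Hz and HF over 0.15-0.4 Hz, in ms^2;
#' their ratio indexes sympathovagal balance. LF needs at least 2 min of
#' signal and HF at least 1 min; below that the feature is undefined (`NA`),
#' as is the ratio when HF is zero.
#'
#' @param series An `rr_series`, fully consistent over the stretch analysed.
#' @param resample_hz Uniform resampling rate in Hz.
#' @return A named list with `lf_power`, `hf_power` (ms^2) and `lf_hf_ratio`.
#' @export
spectral_powers <- function(series, resample_hz = 8) {
  series <- as_rr_series(series)
  n <- nrow(series)
  dur <- if (n >= 2) series$time[n] - series$time[1] else 0
  if (n < 4 || dur < 60) {
    return(list(lf_power = NA_real_, hf_power = NA_real_,
                lf_hf_ratio = NA_real_))
  }
  tg <- seq(series$time[1], series$time[n], by = 1 / resample_hz)
  x <- stats::spline(series$time, series$rr * 1000, xout = tg)$y
  x <- x - mean(x)
  psd <- welch_psd(x, fs = resample_hz, seg_len = min(length(x), 120 * resample_hz))
  band <- function(lo, hi) {
    sel <- psd$freq >= lo & psd$freq < hi
    sum(psd$power[sel]) * psd$df
  }
  hf <- band(0.15, 0.4 + 1e-12)
  lf <- if (dur >= 120) band(0.04, 0.15) else NA_real_
  ratio <- if (is.na(lf) || hf == 0) NA_real_ else lf / hf
  list(lf_power = lf, hf_power = hf, lf_hf_ratio = ratio)
}

# Welch PSD: Hann-windowed overlapping segments, one-sided density.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  scale <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- abs(fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)] # fold negative frequencies
    acc <- acc + p
  }
  df <- fs / seg_len
  list(freq = (seq_len(nf) - 1L) * df, power = acc / length(starts), df = df)
}

#' Sliding-window HRV feature extraction
#'
#' Cuts the series into windows of `window_s` seconds advanced by `step_s`
#' (defaults: 5-min windows, 1-min slide — the sliding overlap avoids edge
#' discontinuities and suits quasi-real-time analysis) and computes the full
#' feature vector per window: SDNN, RMSSD, NN50/pNN50, LF, HF, LF/HF, SD1,
#' SD2 and the beat count. Short tail windows are dropped.
#'
#' @param series An `rr_series`.
#' @param window_s,step_s Window length and slide in seconds.
#' @param t0 Optional vector of window start times, overriding the regular
#'   grid (used to force identical windows across differently reconstructed
#'   versions of the same recording).
#' @param resample_hz Resampling rate for the spectral features.
#' @return A tibble with one row per window (`t0` plus the features above).
#'   Zero rows, with a warning, when the series is shorter than one window.
#' @examples
#' s <- simulate_rr(duration_s = 900, seed = 1)
#' hrv_features(s) # 11 windows
#' @export
hrv_features <- function(series, window_s = 300, step_s = 60, t0 = NULL,
                         resample_hz = 8) {
  series <- as_rr_series(series)
  dur <- if (nrow(series)) max(series$time) else 0
  if (is.null(t0)) {
    if (dur < window_s) {
      warning(sprintf("series (%.0f s) shorter than one %g-s window", dur,
                      window_s), call. = FALSE)
      t0 <- numeric(0)
    } else {
      t0 <- seq(0, dur - window_s, by = step_s)
    }
  }
  purrr::map_dfr(t0, function(start) {
    w <- series[series$time >= start & series$time < start + window_s, ]
    iv <- w$rr
    p <- pnn50(iv)
    po <- poincare_sd(iv)
    sp <- spectral_powers(w, resample_hz)
    tibble::tibble(t0 = start, n_beats = nrow(w),
                   sdnn = sdnn(iv), rmssd = rmssd(iv),
                   nn50 = p$nn50, pnn50 = p$pnn50,
                   lf_power = sp$lf_power, hf_power = sp$hf_power,
                   lf_hf_ratio = sp$lf_hf_ratio,
                   sd1 = po$sd1, sd2 = po$sd2)
  })
}

#' Pairwise products and ratios of HRV features
#'
#' Expands a feature table by every unordered pair of base features `(f, g)`:
#' one product column `f_x_g` and one ratio column `f_over_g` (order of
#' appearance in `cols`). Ratios with a zero denominator become `NA` rather
#' than infinities. Not every engineered column has a physiological reading;
#' the downstream classifier is left to pick the informative ones.
#'
#' @param features A tibble of feature windows, e.g. from [hrv_features()].
#' @param cols Character vector of base feature columns to expand; defaults
#'   to all standard HRV features present.
#' @return The input tibble with the engineered columns appended: `k` base
#'   features yield `k (k - 1)` new columns.
#' @examples
#' f <- tibble::tibble(sdnn = c(50, 60), rmssd = c(30, 35))
#' engineer_features(f) # adds sdnn_x_rmssd and sdnn_over_rmssd
#' @export
engineer_features <- function(features, cols = NULL) {
  std <- c("sdnn", "rmssd", "nn50", "pnn50", "lf_power", "hf_power",
           "lf_hf_ratio", "sd1", "sd2")
  cols <- cols %||% intersect(std, names(features))
  stopifnot(length(cols) >= 2, all(cols %in% names(features)))
  out <- features
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (b <= a) next
      f <- features[[cols[a]]]
      g <- features[[cols[b]]]
      out[[paste0(cols[a], "_x_", cols[b])]] <- f * g
      ratio <- ifelse(g == 0, NA_real_, f / g)
      out[[paste0(cols[a], "_over_", cols[b])]] <- ratio
    }
  }
  out
}
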
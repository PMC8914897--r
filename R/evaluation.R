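#' F1 score
#'
#' `f1_from_counts()` computes `TP / (TP + (FP + FN) / 2)` from a confusion
#' count; `f1_score()` computes it from truth/prediction vectors with a
#' designated positive class.
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts.
#' @return A number in `[0, 1]` (`NA` when the denominator is zero).
#' @examples
#' f1_from_counts(6, 2, 2) # 0.75
#' @export
f1_from_counts <- function(tp, fp, fn) {
  den <- tp + (fp + fn) / 2
  if (den == 0) return(NA_real_)
  tp / den
}

#' @rdname f1_from_counts
#' @param truth,predicted Vectors of class labels.
#' @param positive The positive class (default `"stress"`).
#' @export
f1_score <- function(truth, predicted, positive = "stress") {
  f1_from_counts(sum(truth == positive & predicted == positive),
                 sum(truth != positive & predicted == positive),
                 sum(truth == positive & predicted != positive))
}

#' Reconstruct a degraded series with a named method
#'
#' `"dvc"` runs the full pipeline: [filter_ectopics()] then [impute_dvc()].
#' The interpolation baselines follow the standard recipe instead: every
#' non-physiological interval is simply deleted (timestamp included) and the
#' gaps are filled by [impute_interpolation()]; `"deletion"` stops after the
#' deletion step.
#'
#' @param series An `rr_series` (typically degraded).
#' @param method One of `"dvc"`, `"linear"`, `"pchip"`, `"spline"`,
#'   `"deletion"`.
#' @param bounds A [physio_bounds()] object.
#' @param rng_seed Seed for the DVC gap sampler (ignored by the deterministic
#'   baselines).
#' @return A reconstructed `rr_series`.
#' @export
reconstruct <- function(series,
                        method = c("dvc", "linear", "pchip", "spline", "deletion"),
                        bounds = physio_bounds(), rng_seed = 1L) {
  method <- match.arg(method)
  series <- as_rr_series(series)
  if (method == "dvc") {
    return(impute_dvc(filter_ectopics(series, bounds), bounds, rng_seed))
  }
  keep <- series$rr >= bounds$rr_min & series$rr <= bounds$rr_max
  cleaned <- new_rr_series(series[keep, c("time", "rr")],
                           label = rr_label(series))
  if (method == "deletion") return(cleaned)
  impute_interpolation(cleaned, method, bounds)
}

#' Per-window feature error between original and reconstructed series
#'
#' Features are extracted from both series on the original's window grid and
#' compared window by window: `|f_rec - f_orig| / |f_orig|` per feature
#' (undefined when the original feature is zero or missing).
#'
#' @param original,reconstructed Two `rr_series` spanning the same time range.
#' @param window_s,step_s Window geometry passed to [hrv_features()].
#' @param features Which feature columns to compare.
#' @return A long tibble: `t0`, `feature`, `original`, `reconstructed`,
#'   `rel_error`.
#' @export
reconstruction_error <- function(original, reconstructed,
                                 window_s = 300, step_s = 60,
                                 features = c("sdnn", "rmssd", "pnn50",
                                              "lf_power", "hf_power",
                                              "sd1", "sd2")) {
  fo <- hrv_features(original, window_s, step_s)
  fr <- hrv_features(reconstructed, window_s, step_s, t0 = fo$t0)
  long <- function(df, nm) {
    tidyr::pivot_longer(df[, c("t0", features)], -"t0",
                        names_to = "feature", values_to = nm)
  }
  dplyr::mutate(
    dplyr::inner_join(long(fo, "original"), long(fr, "reconstructed"),
                      by = c("t0", "feature")),
    rel_error = ifelse(is.na(.data$original) | .data$original == 0, NA_real_,
                       abs(.data$reconstructed - .data$original) /
                         abs(.data$original)))
}

#' Evaluation grid specification
#'
#' @param missing_pcts Percentages of deleted beats to sweep (default 5-35 in
#'   steps of 5).
#' @param ectopic_pct Percentage of injected ectopics (default 5).
#' @param methods Reconstruction methods to compare.
#' @param seed Integer seed driving the split, the degradations and the
#'   classifier.
#' @return A list of class `eval_grid`.
#' @export
eval_grid <- function(missing_pcts = seq(5, 35, by = 5), ectopic_pct = 5,
                      methods = c("dvc", "pchip", "linear", "spline"),
                      seed = 1L) {
  stopifnot(length(missing_pcts) > 0, length(methods) > 0)
  structure(list(missing_pcts = missing_pcts, ectopic_pct = ectopic_pct,
                 methods = methods, seed = as.integer(seed)),
            class = "eval_grid")
}

#' Default random-forest hyper-parameters
#'
#' The tuned values shipped as a preset so the grid search can be skipped:
#' 500 trees, 60% of the features considered per split, and a minimal node
#' size of 3.
#'
#' @return A named list understood by [run_grid()] and [tune_rf()].
#' @export
rf_preset <- function() {
  list(num.trees = 500L, mtry_frac = 0.6, min.node.size = 3L)
}

#' Tune the random forest by cross-validated grid search
#'
#' Exhaustive search over tree count, per-split feature fraction and minimal
#' node size, scored by mean F1 over `folds` stratified cross-validation
#' folds.
#'
#' @param data A feature tibble with a `label` column.
#' @param grid A data frame of hyper-parameter combinations (columns
#'   `num.trees`, `mtry_frac`, `min.node.size`); a small default is provided.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed.
#' @param positive Positive class for F1.
#' @return The best row of `grid` as a list, with its `cv_f1` attached.
#' @export
tune_rf <- function(data, grid = NULL, folds = 10L, seed = 1L,
                    positive = "stress") {
  grid <- grid %||% expand.grid(num.trees = c(300L, 500L),
                                mtry_frac = c(0.3, 0.6),
                                min.node.size = c(1L, 3L, 5L))
  withr::with_seed(seed, {
    fold_id <- integer(nrow(data))
    for (lb in unique(data$label)) {
      rows <- which(data$label == lb)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    scores <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
      f1s <- purrr::map_dbl(seq_len(folds), function(k) {
        tr <- data[fold_id != k, ]
        te <- data[fold_id == k, ]
        fit <- fit_rf(tr, as.list(grid[g, ]), seed = seed + k)
        f1_score(te$label, predict_rf(fit, te), positive)
      })
      mean(f1s, na.rm = TRUE)
    })
    best <- as.list(grid[which.max(scores), ])
    best$cv_f1 <- max(scores)
    best
  })
}

fit_rf <- function(data, hyper, seed = 1L) {
  feats <- setdiff(names(data), "label")
  data$label <- factor(data$label)
  p <- length(feats)
  ranger::ranger(
    dependent.variable.name = "label",
    data = data.frame(data[, c(feats, "label")]),
    num.trees = hyper$num.trees,
    mtry = max(1L, min(p, ceiling(hyper$mtry_frac * p))),
    min.node.size = hyper$min.node.size,
    splitrule = "gini", seed = seed,
    respect.unordered.factors = TRUE)
}

predict_rf <- function(fit, data) {
  as.character(predict(fit, data.frame(data))$predictions)
}

#' Compare reconstruction methods by downstream classification F1
#'
#' The full validation experiment: features are extracted from the original
#' labelled corpus, split 80/20 into training and validation windows
#' (stratified by label), and a random forest is trained on the training
#' windows only. Each series is then degraded once per missing percentage
#' (deletion plus ectopic injection), reconstructed by every method from the
#' *same* degraded signal, re-featurised on the original window grid, and the
#' trained model is evaluated on the same validation windows for every
#' method — so methods differ only in how they repaired the signal. Feature
#' columns that are undefined in more than 20% of training windows are
#' dropped; remaining missing values are filled with training-set medians.
#'
#' @param corpus A list of labelled `rr_series` (both classes present, at
#'   least a handful of series each).
#' @param grid An [eval_grid()].
#' @param hyper Hyper-parameters ([rf_preset()] by default) or the result of
#'   [tune_rf()].
#' @param tune Run the cross-validated grid search instead of using `hyper`.
#' @param window_s,step_s Window geometry.
#' @param engineer Append pairwise products/ratios ([engineer_features()]).
#' @param bounds A [physio_bounds()] object.
#' @return An `hrv_grid` object: `f1` (tibble: `missing_pct`, `method`, `f1`),
#'   `f1_original`, the hyper-parameters used, and the validation keys.
#'   [tidy()] returns the F1 table, [glance()] a one-row summary,
#'   [autoplot()] the F1-versus-missing curve per method.
#' @export
run_grid <- function(corpus, grid = eval_grid(), hyper = rf_preset(),
                     tune = FALSE, window_s = 300, step_s = 60,
                     engineer = TRUE, bounds = physio_bounds()) {
  labels <- purrr::map_chr(corpus, ~ rr_label(.x) %||% NA_character_)
  if (anyNA(labels) || length(unique(labels)) < 2) {
    stop("corpus must be labelled and contain both classes", call. = FALSE)
  }

  featurise <- function(series_list, ids, t0s = NULL) {
    purrr::map2_dfr(series_list, ids, function(s, id) {
      f <- hrv_features(s, window_s, step_s,
                        t0 = if (is.null(t0s)) NULL else t0s[[id]])
      if (nrow(f)) {
        dplyr::mutate(if (engineer) engineer_features(f) else f,
                      series = id, label = rr_label(s) %||% labels[[id]],
                      .before = 1)
      } else {
        f
      }
    })
  }

  orig <- featurise(corpus, seq_along(corpus))
  t0s <- split(orig$t0, orig$series)
  t0s <- t0s[order(as.integer(names(t0s)))]

  # stratified 80/20 window split
  val_rows <- withr::with_seed(grid$seed, {
    unlist(lapply(unique(orig$label), function(lb) {
      rows <- which(orig$label == lb)
      sample(rows, max(1L, round(0.2 * length(rows))))
    }))
  })
  key <- paste(orig$series, orig$t0)
  val_keys <- key[val_rows]

  feat_cols <- setdiff(names(orig), c("series", "t0", "label"))
  train <- orig[-val_rows, ]
  na_frac <- purrr::map_dbl(train[feat_cols], ~ mean(is.na(.x)))
  feat_cols <- feat_cols[na_frac <= 0.2]
  med <- purrr::map_dbl(train[feat_cols], ~ median(.x, na.rm = TRUE))
  prep <- function(df) {
    out <- df[, c("label", feat_cols)]
    for (cl in feat_cols) {
      v <- out[[cl]]
      v[is.na(v) | is.infinite(v)] <- med[[cl]]
      out[[cl]] <- v
    }
    out$label <- factor(out$label)
    out
  }

  if (tune) hyper <- tune_rf(prep(train), seed = grid$seed)
  fit <- fit_rf(prep(train), hyper, seed = grid$seed)
  validate <- function(df, keys) {
    sel <- match(val_keys, keys)
    if (anyNA(sel)) stop("validation windows missing from a reconstruction",
                         call. = FALSE)
    d <- df[sel, ]
    f1_score(d$label, predict_rf(fit, prep(d)))
  }
  f1_original <- validate(orig, key)

  rows <- list()
  for (pct in grid$missing_pcts) {
    degraded <- purrr::imap(corpus, function(s, i) {
      degrade(s, missing_pct = pct, ectopic_pct = grid$ectopic_pct,
              seed = grid$seed * 97L + pct * 7L + i, bounds = bounds)
    })
    for (m in grid$methods) {
      rec <- purrr::imap(degraded, function(s, i) {
        reconstruct(s, m, bounds, rng_seed = grid$seed * 13L + pct + i)
      })
      f <- featurise(rec, seq_along(rec), t0s = t0s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        missing_pct = pct, method = m,
        f1 = validate(f, paste(f$series, f$t0)))
    }
  }

  structure(list(f1 = dplyr::bind_rows(rows), f1_original = f1_original,
                 hyper = hyper, grid = grid, validation_keys = val_keys,
                 n_windows = nrow(orig), n_features = length(feat_cols)),
            class = "hrv_grid")
}

#' @export
print.hrv_grid <- function(x, ...) {
  cat(sprintf("HRV reconstruction comparison: F1 = %.3f on original data\n",
              x$f1_original))
  print(tidyr::pivot_wider(x$f1, names_from = "method", values_from = "f1"))
  invisible(x)
}

#' @method tidy hrv_grid
#' @export
tidy.hrv_grid <- function(x, ...) x$f1

#' @method glance hrv_grid
#' @export
glance.hrv_grid <- function(x, ...) {
  tibble::tibble(f1_original = x$f1_original, n_windows = x$n_windows,
                 n_features = x$n_features,
                 n_methods = length(unique(x$f1$method)),
                 n_levels = length(unique(x$f1$missing_pct)))
}
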
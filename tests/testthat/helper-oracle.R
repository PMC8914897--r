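# Independent re-implementation of the ectopic-repair decision table, used as
# a cross-check oracle for filter_ectopics(). Deliberately different
# mechanics from the production code: beats carry persistent ids, each pass
# iterates ids (not positions), every decision is recomputed from scratch on
# a fresh data frame, and actions are applied functionally.

oracle_decide <- function(df, pos, bounds, tol = 1e-9) {
  rr <- df$rr
  tm <- df$time
  n <- nrow(df)
  if (rr[pos] > bounds$rr_max) return(list(action = "delete_long"))
  if (rr[pos] >= bounds$rr_min) return(list(action = "none"))

  adj_ok <- function(j) j >= 2 && j <= n && abs(tm[j] - tm[j - 1] - rr[j]) <= tol
  phys <- function(v) v >= bounds$rr_min && v <= bounds$rr_max
  r_ok <- pos < n && adj_ok(pos + 1) && phys(rr[pos + 1])
  l_ok <- pos > 1 && adj_ok(pos) && phys(rr[pos - 1])

  # deviation budget: mean |successive relative difference| over up to
  # `lookback` pairs before pos, capped
  pair_hi <- pos - 1
  pair_lo <- max(2, pos - bounds$lookback)
  e10 <- if (pair_hi < 2) bounds$max_deviation else {
    ks <- pair_lo:pair_hi
    min(mean(abs(rr[ks] - rr[ks - 1]) / rr[ks - 1]), bounds$max_deviation)
  }

  cand <- function(side) {
    nb <- if (side == "right") pos + 1 else pos - 1
    m <- rr[pos] + rr[nb]
    succ_i <- if (side == "right") pos + 2 else pos + 1
    pred_i <- if (side == "right") pos - 1 else pos - 2
    es <- if (succ_i <= n) abs(rr[succ_i] - m) / m else NA_real_
    ep <- if (pred_i >= 1) abs(m - rr[pred_i]) / rr[pred_i] else NA_real_
    list(m = m, es = es, ep = ep,
         dev_ok = (is.na(es) || es <= e10) && (is.na(ep) || ep <= e10),
         dev40 = (is.na(es) || es <= bounds$max_deviation) &&
           (is.na(ep) || ep <= bounds$max_deviation),
         strict = m > bounds$rr_min && m < bounds$rr_max,
         within = m <= bounds$rr_max,
         etot = sum(es, ep, na.rm = TRUE))
  }
  R <- if (r_ok) cand("right") else NULL
  L <- if (l_ok) cand("left") else NULL

  if (!is.null(R) && R$strict && R$dev_ok) {
    return(list(action = "right_merge", merged = R$m))
  }
  if (!is.null(L) && L$strict && L$dev_ok) {
    return(list(action = "left_merge", merged = L$m))
  }
  if (!is.null(R) && !is.null(L)) {
    if (!R$within && !L$within) return(list(action = "delete_pair"))
    if (R$within && !L$within) return(list(action = "forced_right", merged = R$m))
    if (!R$within && L$within) return(list(action = "forced_left", merged = L$m))
    # both within rr_max: drop the deviation conditions (right first) unless
    # a side deviates beyond the 40% ceiling on either neighbour
    if (R$dev40) return(list(action = "forced_right", merged = R$m))
    if (L$dev40) return(list(action = "forced_left", merged = L$m))
    if (R$etot <= L$etot) return(list(action = "least_error_right", merged = R$m))
    return(list(action = "least_error_left", merged = L$m))
  }
  if (!is.null(R)) {
    if (R$within) return(list(action = "forced_right", merged = R$m))
    return(list(action = "delete_pair"))
  }
  if (!is.null(L)) {
    if (L$within) return(list(action = "forced_left", merged = L$m))
    return(list(action = "delete_unmergeable"))
  }
  list(action = "delete_unmergeable")
}

oracle_apply <- function(df, pos, dec) {
  switch(dec$action,
    delete_long = ,
    delete_unmergeable = list(df = df[-pos, ], fresh = integer(0)),
    delete_pair = list(df = df[-c(pos, min(pos + 1, nrow(df))), ],
                       fresh = integer(0)),
    right_merge = ,
    forced_right = ,
    least_error_right = {
      df$rr[pos + 1] <- dec$merged
      list(df = df[-pos, ], fresh = df$id[pos + 1])
    },
    left_merge = ,
    forced_left = ,
    least_error_left = {
      df$rr[pos] <- dec$merged
      list(df = df[-(pos - 1), ], fresh = integer(0))
    })
}

oracle_filter <- function(time, rr, bounds = physio_bounds(), tol = 1e-9,
                          max_passes = 5) {
  df <- data.frame(id = seq_along(rr), time = time, rr = rr)
  for (pass in seq_len(max_passes)) {
    fresh <- integer(0)
    acted <- FALSE
    for (id in df$id) {
      pos <- match(id, df$id)
      if (is.na(pos) || id %in% fresh) next
      dec <- oracle_decide(df, pos, bounds, tol)
      if (dec$action == "none") next
      acted <- TRUE
      res <- oracle_apply(df, pos, dec)
      df <- res$df
      fresh <- c(fresh, res$fresh)
    }
    if (!acted) break
  }
  df
}
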
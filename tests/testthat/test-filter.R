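test_that("local deviation budget follows the capped successive-difference rule", {
  const <- series_from_rr(rep(0.8, 12))
  expect_equal(local_mean_deviation(const, 12), 0)

  alt <- series_from_rr(rep(c(0.5, 1.0), 6))
  # raw mean of |delta|/previous is (1.0 + 0.5)/2 = 0.75, capped at 0.4
  expect_equal(local_mean_deviation(alt, 12), 0.4)

  expect_equal(local_mean_deviation(const, 2), 0.4) # no preceding pairs

  # with fewer than `lookback` pairs, use what exists
  short <- series_from_rr(c(0.8, 1.0, 0.9))
  expect_equal(local_mean_deviation(short, 3), 0.25)
})

test_that("merge candidates carry conserved values and both deviations", {
  s <- rr_series(time = c(0.8, 1.0, 1.7), rr = c(0.8, 0.2, 0.7))
  r <- evaluate_merge(s, 2, "right")
  expect_equal(r$merged_value, 0.9)
  expect_true(is.na(r$err_succ)) # no beat after the merge target
  expect_equal(r$err_pred, abs(0.9 - 0.8) / 0.8)
  expect_equal(r$err_total, r$err_pred)

  l <- evaluate_merge(s, 2, "left")
  expect_equal(l$merged_value, 1.0)
  expect_equal(l$err_succ, abs(0.7 - 1.0) / 1.0)
  expect_true(is.na(l$err_pred))

  expect_error(evaluate_merge(s, 1, "right"), "below rr_min")
  edge <- rr_series(time = c(0.2, 0.9), rr = c(0.2, 0.7))
  expect_error(evaluate_merge(edge, 1, "left"), "neighbour")
})

test_that("clean series pass through untouched", {
  s <- series_from_rr(c(0.8, 0.8, 0.8))
  f <- filter_ectopics(s)
  expect_equal(f$rr, s$rr)
  expect_equal(f$time, s$time)
  expect_identical(nrow(tidy(f)), 0L)

  empty <- filter_ectopics(rr_series(numeric(0), numeric(0)))
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(tidy(empty)), 0L)
})

test_that("over-long intervals are deleted, leaving a gap", {
  s <- series_from_rr(c(0.8, 1.5, 0.8))
  f <- filter_ectopics(s)
  expect_identical(nrow(f), 2L)
  expect_equal(tidy(f)$action, "delete_long")
  expect_identical(nrow(detect_gaps(f)), 1L)
})

test_that("a right merge absorbs the ectopic and preserves consistency", {
  s <- rr_series(time = c(0.8, 1.0, 1.7), rr = c(0.8, 0.2, 0.7))
  f <- filter_ectopics(s)
  expect_equal(f$rr, c(0.8, 0.9))
  expect_equal(f$time, c(0.8, 1.7))
  expect_equal(tidy(f)$action, "right_merge")
  expect_consistent(f)
})

test_that("both merges over-long forces deletion of the pair", {
  s <- series_from_rr(c(1.2, 0.25, 1.2))
  f <- filter_ectopics(s)
  expect_equal(f$rr, 1.2)
  expect_equal(tidy(f)$action, "delete_pair")
})

test_that("merges conserve the summed interval and the spanned time exactly", {
  # a spurious extra peak splits one interval in two; merging conserves the
  # sum and span whichever side wins, and a right merge is an exact inverse
  for (seed in c(11, 21, 31)) {
    s <- simulate_rr(120, seed = seed)
    d <- degrade(s, missing_pct = 0, ectopic_pct = 5, seed = seed + 1)
    f <- filter_ectopics(d)
    expect_identical(nrow(f), nrow(s))
    expect_equal(sum(f$rr), sum(d$rr), tolerance = 1e-12)
    expect_equal(max(f$time), max(s$time), tolerance = 1e-12)
    expect_consistent(f)
    # the occasional least-error left merge may differ; most beats restore
    expect_gte(mean(abs(f$rr - s$rr) < 1e-12), 0.9)
  }
})

test_that("filtering clears all out-of-bounds intervals and is idempotent", {
  for (seed in 1:5) {
    s <- simulate_rr(120, mean_rr = 0.75, seed = seed)
    d <- degrade(s, missing_pct = 10, ectopic_pct = 5, seed = seed + 50)
    f <- filter_ectopics(d)
    expect_in_bounds(f)
    expect_consistent(f)
    again <- filter_ectopics(f)
    expect_equal(again$rr, f$rr)
    expect_equal(again$time, f$time)
    expect_identical(nrow(tidy(again)), 0L)
  }
})

test_that("every out-of-bounds input interval is accounted for in the report", {
  s <- simulate_rr(180, seed = 21)
  d <- degrade(s, missing_pct = 5, ectopic_pct = 5, seed = 22)
  n_bad <- sum(d$rr < 0.3 | d$rr > 1.3)
  f <- filter_ectopics(d)
  rep <- tidy(f)
  # each action resolves exactly one offending interval (delete_pair's partner
  # is in bounds), and cascading merges can only add actions in later passes
  expect_gte(nrow(rep), n_bad)
  expect_equal(sum(rep$before < 0.3 | rep$before > 1.3), nrow(rep))
})

test_that("the production filter matches the rule-table oracle on random grids", {
  grid_vals <- c(0.2, 0.25, 0.4, 0.8, 1.25, 1.4)
  set.seed(4711)
  for (rep in 1:300) {
    n <- sample(1:6, 1)
    rr <- sample(grid_vals, n, replace = TRUE)
    tm <- cumsum(rr)
    prod <- filter_ectopics(rr_series(tm, rr))
    ora <- oracle_filter(tm, rr)
    expect_equal(prod$time, ora$time, info = paste(rr, collapse = ","))
    expect_equal(prod$rr, ora$rr, info = paste(rr, collapse = ","))
  }
})
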
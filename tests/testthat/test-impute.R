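test_that("gap detection finds every over-long adjacency, in order", {
  expect_identical(nrow(detect_gaps(series_from_rr(rep(0.8, 10)))), 0L)

  s <- rr_series(time = c(1.0, 1.8, 6.0), rr = c(1.0, 0.8, 0.8))
  g <- detect_gaps(s)
  expect_equal(g$t_start, 1.8)
  expect_equal(g$t_end, 6.0)
  expect_equal(g$rr_end, 0.8)

  two <- series_with_deletions(rep(0.8, 30), drop = c(5, 6, 20))
  gg <- detect_gaps(two)
  expect_identical(nrow(gg), 2L)
  expect_true(all(diff(gg$t_start) > 0))
})

test_that("the local Gaussian is fitted on the lookback window before the gap", {
  s <- series_with_deletions(rep(0.8, 20), drop = 12:14)
  gap <- detect_gaps(s)[1, ]
  p <- fit_local_gaussian(s, gap)
  expect_equal(p$mu, 0.8)
  expect_equal(p$sigma, 0)
  expect_equal(p$n_source, 10L)

  s2 <- rr_series(time = c(0.7, 1.6, 6.0), rr = c(0.7, 0.9, 0.8))
  p2 <- fit_local_gaussian(s2, detect_gaps(s2)[1, ])
  expect_equal(p2$mu, 0.8)
  expect_equal(p2$sigma, 0.2 / sqrt(2), tolerance = 1e-9)
  expect_equal(p2$n_source, 2L)

  # gap at the series start: fall back to the data after it
  s3 <- rr_series(time = c(10, 10.8, 11.6), rr = c(0.7, 0.8, 0.8))
  p3 <- fit_local_gaussian(s3, list(t_start = 2, t_end = 10))
  expect_equal(p3$mu, mean(c(0.7, 0.8, 0.8)))
})

test_that("a residual already below rr_max closes in a single deterministic beat", {
  # t_end - rr_end leaves 0.9 s to t_start: no sampling needed
  s <- rr_series(time = c(cumsum(rep(0.8, 10)), 8 + 1.7),
                 rr = c(rep(0.8, 10), 0.8))
  gap <- detect_gaps(s)[1, ]
  res <- fill_gap(s, gap, rng_seed = 1)
  expect_identical(res$log$n_inserted, 1L)
  ins <- res$series[!res$series$time %in% s$time, ]
  expect_equal(ins$rr, 0.9)
  expect_consistent(res$series)
})

test_that("zero-sigma filling is the deterministic limit and tiles exactly", {
  s <- rr_series(time = c(cumsum(rep(0.8, 10)), 8 + 4.0),
                 rr = c(rep(0.8, 10), 0.8))
  gap <- detect_gaps(s)[1, ]
  res <- fill_gap(s, gap, params = list(mu = 0.8, sigma = 0), rng_seed = 5)
  ins <- res$series[!res$series$time %in% s$time, ]
  expect_equal(ins$rr, rep(0.8, 4)) # 3.2 s residual = 4 beats of 0.8
  expect_consistent(res$series)
  expect_equal(min(ins$time) - gap$t_start, ins$rr[1], tolerance = 1e-9)
})

test_that("filled gaps are consistent, in bounds, seeded and span-conserving", {
  s <- rr_series(time = c(cumsum(rep(0.8, 12)), 9.6 + 4.2),
                 rr = c(rep(0.8, 12), 0.8))
  gap <- detect_gaps(s)[1, ]
  params <- list(mu = 0.8, sigma = 0.05)
  a <- fill_gap(s, gap, params, rng_seed = 42)
  b <- fill_gap(s, gap, params, rng_seed = 42)
  c <- fill_gap(s, gap, params, rng_seed = 43)
  expect_identical(a$series$rr, b$series$rr)
  expect_false(identical(a$series$rr, c$series$rr))
  expect_consistent(a$series)
  expect_in_bounds(a$series)
  ins <- a$series[!a$series$time %in% s$time, ]
  expect_equal(sum(ins$rr), gap$span - gap$rr_end, tolerance = 1e-9)
  expect_equal(min(ins$time) - gap$t_start, ins$rr[1], tolerance = 1e-9)
})

test_that("long fills recover the source distribution's mean", {
  pre <- withr::with_seed(7, rnorm(20, 0.8, 0.05))
  span <- 0.8 * 120 + 0.8
  s <- rr_series(time = c(cumsum(pre), sum(pre) + span),
                 rr = c(pre, 0.8))
  gap <- detect_gaps(s)[1, ]
  means <- purrr::map_dbl(1:5, function(seed) {
    res <- fill_gap(s, gap, params = list(mu = 0.8, sigma = 0.05),
                    rng_seed = seed)
    mean(res$series$rr[!res$series$time %in% s$time])
  })
  expect_lt(abs(mean(means) - 0.8), 3 * 0.05 / sqrt(120))
})

test_that("imputation is the identity on gap-free series", {
  s <- series_from_rr(rep(c(0.8, 0.85), 10))
  imp <- impute_dvc(s, rng_seed = 1)
  expect_equal(imp$time, s$time)
  expect_equal(imp$rr, s$rr)
  expect_identical(nrow(fill_log(imp)), 0L)
})

test_that("all gaps are filled and the fill log tracks each one", {
  s <- series_with_deletions(rep(0.8, 40), drop = c(10, 11, 25, 26))
  imp <- impute_dvc(s, rng_seed = 9)
  expect_consistent(imp)
  expect_in_bounds(imp)
  lg <- fill_log(imp)
  expect_identical(nrow(lg), 2L)
  expect_true(all(lg$n_inserted >= 1))
  expect_false(any(lg$forced))
})

test_that("a deleted beat whose span stays below rr_max is restored exactly", {
  rr <- c(rep(0.8, 10), 0.55, 0.6, rep(0.8, 10))
  s <- series_with_deletions(rr, drop = 11) # dT = 1.15 <= rr_max: a mismatch
  expect_identical(length(check_consistency(s)), 1L)
  imp <- impute_dvc(s, rng_seed = 3)
  orig <- series_from_rr(rr)
  expect_equal(imp$time, orig$time, tolerance = 1e-9)
  expect_equal(imp$rr, orig$rr, tolerance = 1e-9)
  expect_identical(fill_log(imp)$kind, "mismatch")
})

test_that("heavy degradation keeps beat count within 10% of the original", {
  for (seed in 1:3) {
    s <- simulate_rr(300, seed = seed)
    d <- degrade(s, missing_pct = 20, ectopic_pct = 0, seed = seed + 10)
    imp <- impute_dvc(filter_ectopics(d), rng_seed = seed)
    expect_lt(abs(nrow(imp) - nrow(s)) / nrow(s), 0.10)
    expect_consistent(imp)
    expect_in_bounds(imp)
  }
})

test_that("the filling procedure terminates on adversarial random gaps", {
  set.seed(2024)
  for (i in 1:400) {
    span <- runif(1, 1.31, 60)
    mu <- runif(1, 0.4, 1.2)
    sigma <- runif(1, 0, 0.3)
    rr_end <- runif(1, 0.3, min(1.3, span - 0.01))
    pre <- rep(mu, 12)
    s <- rr_series(time = c(cumsum(pre), sum(pre) + span),
                   rr = c(pre, rr_end))
    res <- fill_gap(s, detect_gaps(s)[1, ],
                    params = list(mu = mu, sigma = sigma), rng_seed = i)
    expect_consistent(res$series)
  }
})
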
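test_that("time-domain features match hand-computed values", {
  expect_equal(sdnn(rep(0.8, 3)), 0)
  expect_equal(sdnn(c(0.7, 0.9)), sqrt(0.02) * 1000, tolerance = 1e-9)
  expect_true(is.na(sdnn(0.8)))

  expect_equal(rmssd(rep(0.8, 5)), 0)
  expect_equal(rmssd(c(0.8, 0.9)), 100)
  expect_equal(rmssd(c(0.8, 0.9, 0.8)), sqrt(0.02 / 2) * 1000) # = 100

  expect_equal(pnn50(rep(0.8, 4)), list(nn50 = 0L, pnn50 = 0))
  expect_equal(pnn50(c(0.8, 0.9, 0.8)), list(nn50 = 2L, pnn50 = 100))
  expect_equal(pnn50(c(0.80, 0.84, 0.80)), list(nn50 = 0L, pnn50 = 0))

  # order invariance of SDNN
  x <- withr::with_seed(1, runif(50, 0.6, 1.0))
  expect_equal(sdnn(x), sdnn(sample(x)))
})

test_that("features scale linearly with the intervals", {
  x <- withr::with_seed(2, runif(100, 0.6, 1.0))
  for (c in c(0.5, 1.3)) {
    expect_equal(sdnn(c * x), c * sdnn(x), tolerance = 1e-12)
    expect_equal(rmssd(c * x), c * rmssd(x), tolerance = 1e-12)
  }
})

test_that("Poincare axes satisfy the variance identities", {
  expect_equal(poincare_sd(rep(0.8, 5)), list(sd1 = 0, sd2 = 0))

  x <- withr::with_seed(3, rnorm(500, 0.8, 0.05))
  ps <- poincare_sd(x)
  # rotation identity, exact by construction but asserted numerically
  expect_equal((ps$sd1^2 + ps$sd2^2) / 1e6, 2 * var(x), tolerance = 1e-9)
  # i.i.d. intervals: ellipse degenerates towards a circle
  expect_lt(abs(ps$sd1 - sd(x) * 1000), 0.15 * sd(x) * 1000)
  expect_lt(abs(ps$sd2 - sd(x) * 1000), 0.15 * sd(x) * 1000)
  # RMSSD and SD1 measure the same beat-to-beat scatter
  expect_equal(rmssd(x), sqrt(2) * ps$sd1, tolerance = 0.05)

  # strict alternation concentrates all scatter across the identity line
  alt <- rep(c(0.7, 0.9), 25)
  pa <- poincare_sd(alt)
  expect_gt(pa$sd1, 10 * max(pa$sd2, 1e-9))
})

test_that("spectral power lands in the band of the driving modulation", {
  base <- function(f_mod) {
    t <- 0
    rr <- numeric(0)
    while (t < 300) {
      v <- 0.8 + 0.03 * sin(2 * pi * f_mod * t)
      rr <- c(rr, v)
      t <- t + v
    }
    series_from_rr(rr)
  }
  hf_tone <- spectral_powers(base(0.25))
  expect_gt(hf_tone$hf_power / (hf_tone$hf_power + hf_tone$lf_power), 0.95)
  lf_tone <- spectral_powers(base(0.10))
  expect_gt(lf_tone$lf_power / (lf_tone$hf_power + lf_tone$lf_power), 0.95)
  expect_gt(lf_tone$lf_hf_ratio, 1)

  flat <- spectral_powers(series_from_rr(rep(0.8, 400)))
  expect_lt(flat$lf_power + flat$hf_power, 1e-6)
})

test_that("band powers respect the window-length preconditions and Parseval", {
  short <- series_from_rr(rep(0.8, 113)) # ~90 s: HF defined, LF not
  sp <- spectral_powers(short)
  expect_true(is.na(sp$lf_power))
  expect_false(is.na(sp$hf_power))
  expect_true(is.na(spectral_powers(series_from_rr(rep(0.8, 50)))$hf_power))

  s <- simulate_rr(300, seed = 4)
  sp2 <- spectral_powers(s)
  tg <- seq(s$time[1], s$time[nrow(s)], by = 1 / 8)
  x <- stats::spline(s$time, s$rr * 1000, xout = tg)$y
  x <- x - mean(x)
  psd <- hrvdvc:::welch_psd(x, 8, min(length(x), 960))
  total <- sum(psd$power) * psd$df
  expect_lte(sp2$lf_power + sp2$hf_power, total * (1 + 1e-9))
})

test_that("sliding windows follow the 5-min/1-min geometry", {
  s15 <- simulate_rr(905, seed = 5)
  expect_identical(nrow(hrv_features(s15)), 11L)
  s5 <- simulate_rr(302, seed = 6)
  expect_identical(nrow(hrv_features(s5)), 1L)
  expect_warning(f0 <- hrv_features(simulate_rr(240, seed = 7)), "shorter")
  expect_identical(nrow(f0), 0L)

  f <- hrv_features(s15)
  expect_equal(f$t0, seq(0, 600, by = 60))
  expect_true(all(f$nn50 <= f$n_beats - 1))
  expect_true(all(f$pnn50 >= 0 & f$pnn50 <= 100))
})

test_that("feature engineering expands every unordered pair once each way", {
  f <- tibble::as_tibble(setNames(as.data.frame(matrix(runif(40, 1, 2), 5)),
                                  paste0("f", 1:8)))
  out <- engineer_features(f, cols = names(f))
  expect_identical(ncol(out), 64L) # 8 + 2 * choose(8, 2)

  hw <- hrv_features(simulate_rr(310, seed = 8))
  eng <- engineer_features(hw)
  expect_true("rmssd_x_lf_power" %in% names(eng) ||
                "lf_power_x_rmssd" %in% names(eng))
  expect_true(any(grepl("^sdnn_(x|over)_rmssd$|^rmssd_(x|over)_sdnn$",
                        names(eng))))

  z <- tibble::tibble(a = c(1, 2), b = c(0, 4))
  ze <- engineer_features(z, cols = c("a", "b"))
  expect_true(is.na(ze$a_over_b[1]))
  expect_equal(ze$a_over_b[2], 0.5)
})
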
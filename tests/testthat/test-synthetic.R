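test_that("the generator is consistent, seeded and hits its SDNN target", {
  flat <- simulate_rr(60, sdnn_target = 0, lf_amp = 0, hf_amp = 0, seed = 1)
  expect_equal(sdnn(flat$rr), 0)
  expect_consistent(flat)

  s <- simulate_rr(600, sdnn_target = 0.05, seed = 2)
  expect_lt(abs(sdnn(s$rr) - 50) / 50, 0.15)
  expect_consistent(s)
  expect_in_bounds(s)

  expect_identical(simulate_rr(120, seed = 9)$rr, simulate_rr(120, seed = 9)$rr)
  expect_false(identical(simulate_rr(120, seed = 9)$rr,
                         simulate_rr(120, seed = 10)$rr))

  expect_error(simulate_rr(60, mean_rr = 1.25, sdnn_target = 0.05),
               "outside")
  expect_error(simulate_rr(60, sdnn_target = 0.01, lf_amp = 0.05),
               "sinusoids")
})

test_that("condition presets carry their labels and autonomic signatures", {
  rel <- simulate_preset("relax", 400, seed = 3)
  str <- simulate_preset("stress", 400, seed = 3)
  expect_identical(rr_label(rel), "relax")
  expect_identical(rr_label(str), "stress")
  expect_gt(mean(rel$rr), mean(str$rr))
  sp_r <- spectral_powers(rel)
  sp_s <- spectral_powers(str)
  expect_gt(sp_s$lf_hf_ratio, sp_r$lf_hf_ratio)
})

test_that("degradation deletes and injects the exact planned counts", {
  s <- simulate_rr(900, seed = 4) # ~1125 beats
  n <- nrow(s)
  d <- degrade(s, missing_pct = 20, ectopic_pct = 5, seed = 5)
  plan <- degradation_plan(d)
  expect_identical(length(plan$deleted_indices), as.integer(round(0.2 * n)))
  expect_identical(length(plan$ectopic_indices), as.integer(round(0.05 * n)))
  expect_length(intersect(plan$deleted_indices, plan$ectopic_indices), 0)
  # exactly the injected count of sub-rr_min intervals is present afterwards
  expect_identical(sum(d$rr < 0.3), as.integer(round(0.05 * n)))
  expect_identical(nrow(d), n - length(plan$deleted_indices) +
                     length(plan$ectopic_indices))

  id <- degrade(s, 0, 0, seed = 6)
  expect_equal(id$time, s$time)
  expect_equal(id$rr, s$rr)
  expect_error(degrade(s, 55, 0, seed = 1))
  tiny <- series_from_rr(rep(0.4, 20)) # too short to host a split injection
  expect_error(degrade(tiny, 0, 20, seed = 1), "host")
})

test_that("re-inserting the deleted rows restores the original exactly", {
  s <- simulate_rr(300, seed = 7)
  d <- degrade(s, missing_pct = 25, ectopic_pct = 0, seed = 8)
  back <- restore_deletions(d)
  expect_equal(back$time, s$time, tolerance = 1e-12)
  expect_equal(back$rr, s$rr, tolerance = 1e-12)
})

test_that("burst deletion removes the requested count in contiguous runs", {
  s <- simulate_rr(600, seed = 10)
  d <- degrade(s, missing_pct = 20, ectopic_pct = 0, seed = 11, burst = TRUE)
  plan <- degradation_plan(d)
  expect_identical(length(plan$deleted_indices),
                   as.integer(round(0.2 * nrow(s))))
  runs <- rle(diff(plan$deleted_indices) == 1)
  expect_gt(max(c(0, runs$lengths[runs$values])) + 1, 2) # some multi-beat run
})

test_that("DVC tracks the original beat count more closely than interpolation", {
  diff_dvc <- diff_lin <- numeric(4)
  for (seed in 1:4) {
    s <- simulate_rr(300, seed = seed)
    d <- degrade(s, missing_pct = 25, ectopic_pct = 5, seed = seed + 40)
    diff_dvc[seed] <- abs(nrow(reconstruct(d, "dvc", rng_seed = seed)) - nrow(s))
    diff_lin[seed] <- abs(nrow(reconstruct(d, "linear")) - nrow(s))
  }
  expect_lte(median(diff_dvc), median(diff_lin))
})

test_that("the corpus generator produces labelled heterogeneous subjects", {
  corpus <- simulate_corpus(3, 320, seed = 12)
  expect_length(corpus, 6)
  labs <- purrr::map_chr(corpus, rr_label)
  expect_identical(sum(labs == "relax"), 3L)
  means <- purrr::map_dbl(corpus, ~ mean(.x$rr))
  # class distributions overlap (as in real cohorts) but are ordered on average
  expect_gt(mean(means[labs == "relax"]), mean(means[labs == "stress"]))
  expect_gt(length(unique(round(means, 3))), 4) # subjects differ
})
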
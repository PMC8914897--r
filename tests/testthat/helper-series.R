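# build a fully consistent series from intervals alone
series_from_rr <- function(rr, label = NULL) {
  rr_series(time = cumsum(rr), rr = rr, label = label)
}

# a consistent series with the beats at `drop` removed (opens gaps /
# mismatches without touching surviving timestamps)
series_with_deletions <- function(rr, drop) {
  s <- series_from_rr(rr)
  new_rr <- s$rr[-drop]
  rr_series(time = s$time[-drop], rr = new_rr)
}

expect_consistent <- function(series, bounds = physio_bounds()) {
  expect_identical(check_consistency(series, bounds = bounds), integer(0))
}

expect_in_bounds <- function(series, bounds = physio_bounds()) {
  expect_true(all(series$rr >= bounds$rr_min & series$rr <= bounds$rr_max))
}
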
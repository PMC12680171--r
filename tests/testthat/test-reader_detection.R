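test_that("PETH construction places delayed spikes in the right bin", {
  peaks <- seq(10, 307, by = 3)   # spaced beyond the +/- 1 s window
  reader <- peaks + 0.021         # off the bin edge: exactly one hot bin
  p <- compute_peth(reader, peaks)
  expect_equal(sum(p$M), 100)
  hot <- which(p$m > 0)
  expect_length(hot, 1)
  expect_equal(p$m[hot], 100)
  expect_true(all(p$delays_ms[hot] > 10 & p$delays_ms[hot] <= 30))
  expect_false(p$excluded)
  expect_equal(p$m, colSums(p$M))

  # fewer than 30 spikes -> excluded
  p29 <- compute_peth(peaks[1:29] + 0.02, peaks)
  expect_true(p29$excluded)
  expect_error(compute_peth(reader, numeric(0)), "zero activation peaks")
})

test_that("classification needs a positive mode and both bands", {
  peaks <- seq(10, 607, by = 3)
  # responds BEFORE the peaks: mode negative, must fail criterion (c)
  before <- peaks - 0.020
  p <- shuffle_bands(compute_peth(before, peaks), 100, seed = 1)
  v <- classify_reader_pair(p)
  expect_true(v$testable)
  expect_false(v$significant)
  expect_lt(v$mode_delay_ms, 0)

  # responds at +20 ms: significant, first delay inside (10, 30]
  after <- peaks + 0.020
  p2 <- shuffle_bands(compute_peth(after, peaks), 100, seed = 1)
  v2 <- classify_reader_pair(p2)
  expect_true(v2$significant)
  expect_true(v2$first_sig_delay_ms > 10 && v2$first_sig_delay_ms < 30)

  # excluded PETH is not testable
  vex <- classify_reader_pair(compute_peth(peaks[1:5] + 0.02, peaks))
  expect_false(vex$testable)
})

test_that("shuffled bands conserve spike counts and score the response", {
  ses <- small_session()
  peaks <- ses$series$events$peak_s
  p <- shuffle_bands(compute_peth(unit_spikes(ses$spikes, 11), peaks),
                     100, seed = 2)
  # permutation preserves each trial's total: null means must sum to sum(m)
  expect_equal(sum(p$shuffle_mean), sum(p$m), tolerance = 1e-9)
  expect_equal(length(p$pointwise_band), 200)
  expect_gte(p$global_band, max(p$pointwise_band) - 1e-9)
  expect_equal(p$response_score,
               (p$m - p$shuffle_mean) / pmax(p$shuffle_sd, 1e-12))
})

test_that("classification ignores spikes outside the window", {
  peaks <- seq(10, 307, by = 3)
  reader <- peaks + 0.020
  far <- c(reader, seq(400, 500, by = 0.11))   # mass far outside +/- 1 s
  p1 <- shuffle_bands(compute_peth(reader, peaks), 100, seed = 3)
  p2 <- shuffle_bands(compute_peth(far, peaks), 100, seed = 3)
  expect_equal(classify_reader_pair(p1), classify_reader_pair(p2))
})

test_that("delay profile peaks at the planted delay", {
  ses <- small_session()
  peaks <- ses$series$events$peak_s
  peths <- lapply(0:2, function(k)
    shuffle_bands(compute_peth(unit_spikes(ses$spikes, 11), peaks), 100,
                  seed = 10 + k))
  prof <- delay_profile(peths)
  expect_lte(sum(prof$percent), 100 + 1e-9)
  expect_true(prof$delay_ms[which.max(prof$percent)] %in% c(5, 15, 25))
})

test_that("response scores are stable across split halves for real couplings", {
  ses <- small_session()
  peaks <- ses$series$events$peak_s
  s1 <- split_half_response_score(unit_spikes(ses$spikes, 11), peaks,
                                  n_shuffles = 100, seed = 6)
  s2 <- split_half_response_score(unit_spikes(ses$spikes, 11), peaks,
                                  n_shuffles = 100, seed = 6)
  expect_true(s1$testable)
  expect_gt(s1$correlation, 0.3)
  expect_identical(s1$correlation, s2$correlation)   # deterministic
})

test_that("reader response grows with the number of coactive members", {
  ses <- small_session()
  ev <- find_subset_events(ses$spikes, 1:4)
  mc <- member_count_response_curve(unit_spikes(ses$spikes, 11), ev)
  expect_true(mc$trend_defined)
  expect_gt(mc$spearman_rho, 0.2)
  expect_true(all(diff(mc$strata$mean_response) > -1e-9))
  # single-stratum input: trend undefined
  ev1 <- ev[ev$n_active == 1, ]
  attr(ev1, "recruited") <- attr(ev, "recruited")[ev$n_active == 1]
  mc1 <- member_count_response_curve(unit_spikes(ses$spikes, 11), ev1)
  expect_false(mc1$trend_defined)
})

test_that("leaving out the top influencer keeps the response above baseline", {
  ses <- small_session()
  ev <- find_subset_events(ses$spikes, 1:4)
  lk <- leave_k_out_response(unit_spikes(ses$spikes, 11), ev, ses$spikes,
                             ses$epochs, k = 1, members = 1:4)
  expect_true(lk$testable)
  expect_gt(lk$response_rate_hz, lk$baseline_rate_hz)
  expect_error(leave_k_out_response(unit_spikes(ses$spikes, 11), ev,
                                    ses$spikes, ses$epochs, k = 4,
                                    members = 1:4),
               "smaller than the member count")
})
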
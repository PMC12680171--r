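test_that("Hoyer sparsity matches its closed form and limits", {
  expect_equal(hoyer_sparsity(c(0, 0, 1, 0)), 1)
  expect_equal(hoyer_sparsity(rep(0.4, 6)), 0)
  set.seed(3)
  for (i in 1:20) {
    r <- runif(sample(3:8, 1))
    n <- length(r)
    oracle <- (sqrt(n) - sum(r) / sqrt(sum(r^2))) / (sqrt(n) - 1)
    expect_equal(hoyer_sparsity(r), oracle)
    expect_equal(hoyer_sparsity(3.7 * r), hoyer_sparsity(r))  # scale-invariant
    expect_true(hoyer_sparsity(r) >= 0 && hoyer_sparsity(r) <= 1)
  }
  expect_error(hoyer_sparsity(c(0, 0)), "all responses zero")
  expect_error(hoyer_sparsity(5), ">= 2 assemblies")
})

test_that("subset events cluster member spikes at the timescale", {
  sp <- spike_data(c(1, 2, 3, 1, 1, 2),
                   c(0.100, 0.105, 0.112, 0.500, 0.900, 0.908),
                   c("1" = "A", "2" = "A", "3" = "A"))
  ev <- find_subset_events(sp, 1:3, timescale_ms = 15)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$n_active, c(3L, 1L, 2L))
  expect_equal(attr(ev, "recruited")[[1]], c(1, 2, 3))
  expect_equal(ev$peak_s[1], mean(c(0.100, 0.105, 0.112)))
})

test_that("a baseline reader has subset responses near one", {
  ses <- small_session()
  ev <- find_subset_events(ses$spikes, 1:4)
  # unit 15 is an uncoupled B unit
  sr <- subset_responses(unit_spikes(ses$spikes, 15), ev, ses$epochs,
                         n_members = 4)
  expect_true(sr$testable)
  expect_lt(abs(mean(sr$subsets$response) - 1), 0.5)
})

test_that("sigmoid parameters are recovered from sigmoid data", {
  set.seed(8)
  ok <- 0
  for (i in 1:5) {
    x <- rep(seq(1, 12) / 12, each = 1)
    y <- stats::plogis(10 * (x - 0.5)) + rnorm(12, 0, 0.03)
    subsets <- data.frame(subset = as.character(seq_along(x)),
                          n_active = round(x * 12), x = x,
                          response = y, n_events = 50)
    fit <- fit_sigmoid_vs_proportional(subsets)
    # responses get re-normalized by the complete response inside the fit
    if (abs(fit$k - 10) / 10 < 0.4 && abs(fit$x0 - 0.5) < 0.125) ok <- ok + 1
    expect_gt(fit$r2_sigmoid, 0.9)
  }
  expect_gte(ok, 4)
  # F(x0) = 0.5 by construction of the logistic
  expect_equal(stats::plogis(0), 0.5)
})

test_that("proportional data do not favor the sigmoid", {
  set.seed(9)
  x <- seq(0.1, 1, length.out = 10)
  y <- x + rnorm(10, 0, 0.01)
  subsets <- data.frame(subset = as.character(1:10), n_active = round(x * 10),
                        x = x, response = y, n_events = 50)
  fit <- fit_sigmoid_vs_proportional(subsets)
  expect_gt(fit$r2_proportional, 0.98)
  expect_lt(mean(abs(fit$boost)), 0.05)
  expect_error(fit_sigmoid_vs_proportional(subsets[1:3, ]), "4 distinct")
})

test_that("planted completion readers respond sigmoidally to subsets", {
  ses <- small_session()
  ev <- find_subset_events(ses$spikes, 1:4)
  sr <- subset_responses(unit_spikes(ses$spikes, 11), ev, ses$epochs,
                         n_members = 4)
  expect_true(sr$testable)
  ordered <- sr$subsets[order(sr$subsets$n_active), ]
  by_size <- tapply(ordered$response, ordered$n_active, mean)
  expect_true(all(diff(by_size) > 0))
  fit <- fit_sigmoid_vs_proportional(sr$subsets)
  expect_gt(fit$r2_sigmoid, fit$r2_proportional)
})

test_that("the overlap rule needs >= 25% shared members and size > 2", {
  expect_true(assemblies_overlap(1:4, c(1, 2, 5)))      # ABCD vs ABE
  expect_false(assemblies_overlap(1:4, 5:8))            # disjoint
  expect_false(assemblies_overlap(1:2, c(1, 5, 6)))     # too small
  expect_false(assemblies_overlap(1:8, c(1, 9, 10)))    # 1/8 < 25%
})

test_that("discrimination index has its documented endpoints and antisymmetry", {
  set.seed(10)
  peaks1 <- sort(runif(60, 10, 590))
  peaks2 <- sort(runif(60, 10, 590))
  rt <- sort(c(peaks1 + 0.02, runif(300, 0, 600)))   # responds to assembly 1
  ep <- interval_set(0, 600)
  d12 <- discrimination_index(rt, peaks1, peaks2, ep, n_shuffles = 200, seed = 1)
  d21 <- discrimination_index(rt, peaks2, peaks1, ep, n_shuffles = 200, seed = 1)
  expect_true(d12$testable)
  expect_equal(d12$d, -d21$d)
  expect_true(d12$d >= -1 && d12$d <= 1)
  expect_true(d12$significant)
  # null distribution is centered near zero
  expect_lt(abs(stats::median(d12$null)), 0.15)
  # responding only to assembly 1 with no baseline: d = 1
  rt_pure <- peaks1 + 0.02
  d_pure <- discrimination_index(rt_pure, peaks1, peaks2, ep,
                                 n_shuffles = 100, seed = 2)
  expect_equal(d_pure$d, 1)
})

test_that("selective readers grow sparser than the identity shuffle", {
  ses <- small_session()
  peaks <- ses$series$events$peak_s
  set.seed(11)
  others <- lapply(1:3, function(i) sort(runif(length(peaks), 1, 599)))
  all_peaks <- c(list(peaks), others)
  sp_reader <- sparsity_increase(unit_spikes(ses$spikes, 11), all_peaks,
                                 ses$epochs, n_shuffles = 300, seed = 3)
  expect_true(sp_reader$testable)
  expect_gt(sp_reader$increase, 0)
  # a unit driven equally (and stochastically) by all "assemblies" stays
  # near the shuffle; its increase sits well below the selective reader's
  set.seed(12)
  sym <- sort(c(runif(400, 0, 600),
                unlist(lapply(all_peaks, function(p)
                  p[runif(length(p)) < 0.5] + 0.02))))
  sp_sym <- sparsity_increase(sym, all_peaks, ses$epochs,
                              n_shuffles = 300, seed = 3)
  expect_true(sp_sym$testable)
  expect_lt(sp_sym$increase, sp_reader$increase / 2)
  expect_lt(abs(sp_sym$increase), 1)
})
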
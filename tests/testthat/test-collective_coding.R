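test_that("linear readout weights equal the normal-equations solution", {
  ses <- small_session()
  ro <- fit_linear_readout(unit_spikes(ses$spikes, 11), ses$spikes,
                           ses$series, max_triggers = 800)
  # independent oracle: rebuild the design by direct counting and solve
  # the least-squares problem with lm() at two delays
  members <- ro$members
  count_in <- function(times, centers, halfw) {
    vapply(centers, function(c0)
      sum(times >= c0 - halfw & times < c0 + halfw), numeric(1))
  }
  X <- cbind(1, vapply(members, function(m) {
    cnt <- count_in(unit_spikes(ses$spikes, m), ro$triggers_out, 0.0075)
    cnt - as.integer(ro$trigger_members_out == m)
  }, numeric(length(ro$triggers_out))))
  rt <- unit_spikes(ses$spikes, 11)
  for (d_ms in c(20, -500)) {
    y <- count_in(rt, ro$triggers_out + d_ms / 1000, 0.0075)
    w_ora <- unname(stats::lm.fit(X, y)$coefficients)
    i <- which.min(abs(ro$delays_ms - d_ms))
    expect_equal(unname(ro$W[, i]), w_ora, tolerance = 1e-8)
  }
  # eta is the mean prediction over in-assembly triggers
  Xin <- cbind(1, vapply(members, function(m) {
    cnt <- count_in(unit_spikes(ses$spikes, m), ro$triggers_in, 0.0075)
    cnt - as.integer(ro$trigger_members_in == m)
  }, numeric(length(ro$triggers_in))))
  i20 <- which.min(abs(ro$delays_ms - 20))
  expect_equal(ro$eta[i20], mean(Xin %*% ro$W[, i20]), tolerance = 1e-8)
})

test_that("supralinearity separates collective from additive surrogates", {
  ses <- small_session()
  # the independent surrogate is additive by construction: S(20 ms) = 0
  ind <- simulate_independent_reader(ses$spikes, ses$planted$members)
  expect_equal(length(ind),
               sum(ses$spikes$spikes$unit %in% ses$planted$members))
  si_i <- supralinearity_index(fit_linear_readout(ind, ses$spikes, ses$series))
  expect_true(si_i$testable)
  expect_lt(abs(si_i$S20), 0.05)
  # the perfect surrogate responds only to collective events: S(20 ms) >> 0
  pf <- simulate_perfect_reader(ses$series)
  si_p <- supralinearity_index(fit_linear_readout(pf, ses$spikes, ses$series))
  expect_true(si_p$testable)
  expect_gt(si_p$S20, 0)
  expect_gt(si_p$S20, si_p$S_baseline)
})

test_that("the perfect reader applies the half rule with observed subsets", {
  mk_series <- function(n_active, members) {
    ev <- data.frame(start_s = seq_along(n_active), stop_s = seq_along(n_active) + 0.01,
                     peak_s = seq_along(n_active) + 0.005, n_active = n_active)
    structure(list(events = ev, members = members, window = 0.015),
              class = "activation_series")
  }
  # 4-member assembly: events recruiting >= 2 trigger a spike
  s4 <- mk_series(c(1, 2, 3, 4), 1:4)
  expect_length(simulate_perfect_reader(s4), 3)
  # 10-member assembly whose largest observed subset is 4: threshold 2
  s10 <- mk_series(c(1, 2, 2, 4, 3), 1:10)
  expect_length(simulate_perfect_reader(s10), 4)
})

test_that("AB/AA event search follows the consecutive-pair rule", {
  # A at {0, 10 ms}, B silent: one AA event at midpoint 5 ms
  ev <- find_ab_aa_events(c(0, 0.010), numeric(0))
  expect_equal(nrow(ev$aa), 1)
  expect_equal(ev$aa$t_mid, 0.005)
  expect_equal(nrow(ev$ab), 0)
  # A at 0, B at 12 ms: one AB event at midpoint 6 ms
  ev2 <- find_ab_aa_events(0, 0.012)
  expect_equal(nrow(ev2$ab), 1)
  expect_equal(ev2$ab$t_mid, 0.006)
  # A at 0, A at 8 ms, B at 12 ms: AA found, A(8)-B(12) rejected
  ev3 <- find_ab_aa_events(c(0, 0.008), 0.012)
  expect_equal(nrow(ev3$aa), 1)
  expect_equal(nrow(ev3$ab), 0)
  # B-then-A within the window is neither AB nor AA
  ev4 <- find_ab_aa_events(0.012, 0)
  expect_equal(nrow(ev4$ab) + nrow(ev4$aa), 0)
})

test_that("identical AB and AA event sets give a zero difference", {
  set.seed(4)
  rt <- sort(runif(2000, 0, 500))
  mids <- sort(runif(100, 1, 499))
  r <- ab_aa_response(rt, mids, mids)
  expect_true(r$testable)
  expect_equal(r$diff, rep(0, length(r$diff)))
  expect_equal(r$diff_response, 0)
  # too few events: not testable
  expect_false(ab_aa_response(rt, mids[1:5], mids)$testable)
})

test_that("coincidence readers prefer AB over AA only at brief delays", {
  cfg <- synth_config(seed = 51, n_units_a = 8, n_units_b = 4,
                      duration_s = 1200, rate_meanlog = log(2.5),
                      rate_sdlog = 0.2,
                      assemblies = list(synth_assembly(1:5, incidence_hz = 0)),
                      readers = list(synth_reader(9, 1, mode = "coincidence",
                                                  p_max = 0.5),
                                     synth_reader(10, 1, mode = "independent",
                                                  p_max = 0.3)))
  ses <- generate_session(cfg)
  pairs <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1),
                c(2, 1), c(3, 2), c(4, 3), c(5, 4), c(1, 5))
  diff_at <- function(unit, d_ms) {
    out <- c()
    for (pr in pairs) {
      evs <- find_ab_aa_events(unit_spikes(ses$spikes, pr[1]),
                               unit_spikes(ses$spikes, pr[2]),
                               delay_range = c(d_ms - 2.5, d_ms + 2.5) / 1000)
      r <- ab_aa_response(unit_spikes(ses$spikes, unit), evs$ab$t_mid,
                          evs$aa$t_mid, min_events = 10)
      if (isTRUE(r$testable)) out <- c(out, r$diff_response)
    }
    mean(out)
  }
  expect_gt(diff_at(9, 5), 1)          # coincidence reader, brief delay
  expect_lt(abs(diff_at(9, 50)), 1)    # coincidence reader, long delay
  expect_lt(abs(diff_at(10, 5)), 1)    # rate reader everywhere
})
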
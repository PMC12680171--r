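test_that("Marcenko-Pastur bound matches its closed form", {
  expect_equal(marcenko_pastur_bound(100, 10000), 1.21)
  expect_equal(marcenko_pastur_bound(1, 10000), 1.0201)
  expect_error(marcenko_pastur_bound(100, 100), "more bins than units")
})

test_that("white-noise eigenvalues almost never exceed the bound", {
  set.seed(21)
  n <- 30; q <- 3000
  exceed <- vapply(1:100, function(i) {
    X <- matrix(rnorm(n * q), n, q)
    X <- (X - rowMeans(X)) / sqrt(rowMeans(X^2) - rowMeans(X)^2)
    max(eigen(tcrossprod(X) / q, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1)) > marcenko_pastur_bound(n, q)
  expect_lt(mean(exceed), 0.05)
})

test_that("Otsu membership matches an exhaustive oracle", {
  ot <- otsu_members(c(0.9, 0.8, 0.05, 0.04, 0.03))
  expect_setequal(ot$members, 1:2)

  # independent oracle: try every split of the sorted |w| directly
  oracle_otsu <- function(w) {
    s <- sort(abs(w)); n <- length(s); best <- -Inf; thr <- NA
    for (i in 1:(n - 1)) {
      if (s[i] == s[i + 1]) next
      g1 <- s[1:i]; g2 <- s[(i + 1):n]
      v <- (length(g1) / n) * (length(g2) / n) * (mean(g1) - mean(g2))^2
      if (v > best) { best <- v; thr <- (s[i] + s[i + 1]) / 2 }
    }
    list(threshold = thr,
         effectiveness = best / (mean(s^2) - mean(s)^2))
  }
  set.seed(2)
  for (i in 1:20) {
    w <- c(runif(3, 0.5, 1), runif(7, 0, 0.2)) * sample(c(-1, 1), 10, TRUE)
    got <- otsu_members(w)
    ora <- oracle_otsu(w)
    expect_equal(got$threshold, ora$threshold)
    expect_equal(got$effectiveness, ora$effectiveness, tolerance = 1e-12)
    expect_true(got$effectiveness >= 0 && got$effectiveness <= 1)
    expect_setequal(got$members, which(abs(w) > got$threshold))
  }

  # perfectly bimodal weights separate almost completely
  expect_gt(otsu_members(c(rep(0.7, 3), rep(0.01, 7)))$effectiveness, 0.99)
  expect_error(otsu_members(rep(0.3, 5)), "no separation")
})

test_that("planted assemblies are recovered with exact member sets", {
  ses <- small_session()
  expect_gte(length(ses$assemblies), 1)
  expect_setequal(ses$planted$members, 1:4)
  # weight-vector invariants
  for (a in ses$assemblies) {
    expect_equal(sum(a$weights^2), 1, tolerance = 1e-8)
    expect_gt(a$weights[which.max(abs(a$weights))], 0)
    expect_setequal(a$members,
                    as.integer(names(a$weights)[abs(a$weights) > a$otsu_threshold]))
  }
})

test_that("two disjoint planted assemblies are both recovered", {
  cfg <- synth_config(seed = 33, n_units_a = 12, n_units_b = 6,
                      duration_s = 600,
                      assemblies = list(synth_assembly(1:4),
                                        synth_assembly(5:8)),
                      readers = list(synth_reader(13, 1), synth_reader(14, 2)))
  ses <- generate_session(cfg)
  det <- filter_mixed_sign(detect_assemblies(bin_and_zscore(ses$spikes, ses$epochs)))$kept
  match_one <- function(members) {
    best <- 0
    for (a in det) {
      w <- a$weights; tmpl <- stats::setNames(rep(0, length(w)), names(w))
      tmpl[as.character(members)] <- 1 / sqrt(length(members))
      best <- max(best, abs(sum(w * tmpl)))
    }
    best
  }
  expect_gt(match_one(1:4), 0.8)
  expect_gt(match_one(5:8), 0.8)
})

test_that("independent Poisson units yield no assemblies", {
  hits <- vapply(1:5, function(s) {
    sd <- poisson_spikes(15, 400, rate = 2, seed = 100 + s)
    length(detect_assemblies(bin_and_zscore(sd, interval_set(0, 400))))
  }, numeric(1))
  expect_gte(sum(hits == 0), 4)
})

test_that("mixed-sign assemblies are set aside", {
  pos <- make_assembly(c(0.6, 0.7, 0.05, 0.04, 0.03, 0.02))
  mix <- make_assembly(c(0.6, -0.7, 0.05, 0.04, 0.03, 0.02))
  expect_true(pos$sign_valid)
  expect_false(mix$sign_valid)
  f <- filter_mixed_sign(list(pos, mix))
  expect_length(f$kept, 1)
  expect_length(f$discarded, 1)
  expect_true(f$kept[[1]]$sign_valid)
})

test_that("identity shuffling preserves counts and destroys assemblies", {
  ses <- small_session()
  sh <- shuffle_spike_identities(ses$spikes, seed = 3)
  expect_equal(table(sh$spikes$unit), table(ses$spikes$spikes$unit))
  expect_equal(sort(sh$spikes$time), sort(ses$spikes$spikes$time))
  det_sh <- detect_assemblies(bin_and_zscore(sh, ses$epochs))
  expect_lte(length(det_sh), length(ses$assemblies))
  expect_lte(length(det_sh), 1)   # planted structure gone
})

test_that("split-half detection finds matching significant assemblies", {
  ses <- small_session()
  sh <- split_half_crossvalidate(ses$spikes, ses$epochs, seed = 4, n_null = 100)
  expect_gte(nrow(sh$matches), 1)
  expect_true(all(sh$matches$significant))
  expect_true(all(sh$matches$cosine > 0.7))
})

test_that("peer prediction gains separate members from bystanders", {
  ses <- small_session()
  g <- peer_prediction_gain(ses$Z, ses$planted, n_shuffles = 20, seed = 5)
  expect_gt(median(g), 0)
  g0 <- peer_prediction_gain(ses$Z, c(1, 6, 7, 8), n_shuffles = 20, seed = 5)
  expect_lt(median(abs(g0)), 0.02)
  expect_error(peer_prediction_gain(ses$Z, 1), ">= 2 members")
})

test_that("member cross-correlograms peak at brief delays", {
  ses <- small_session()
  ccg <- member_synchrony_ccg(ses$spikes, rbind(c(1, 2), c(1, 3), c(6, 7)),
                              min_spikes = 50)
  memb <- ccg[ccg$unit1 %in% 1:4 & ccg$unit2 %in% 1:4, ]
  ctrl <- ccg[ccg$unit1 %in% 6:10 & ccg$unit2 %in% 6:10, ]
  expect_true(all(abs(memb$mode_ms) <= 15))
  expect_gt(min(memb$peak_z), max(0, if (nrow(ctrl)) 0 else 0))
  # identical trains correlate at zero lag
  t1 <- sort(runif(300, 0, 100))
  sd2 <- spike_data(c(rep(1, 300), rep(2, 300)), c(t1, t1),
                    c("1" = "A", "2" = "A"))
  cc2 <- member_synchrony_ccg(sd2, rbind(c(1, 2)), min_spikes = 50)
  expect_equal(cc2$mode_ms, 2.5)   # lag-0 pairs land in the first bin above 0
})
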
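#' Peri-event time histogram of a reader around activation peaks
#'
#' Spike counts of one unit in 10-ms bins spanning +/- 1 s around each
#' activation peak. The trial x bin matrix `M` and its column sums `m` (the
#' PETH) are returned; PETHs built from fewer than 30 spikes in total are
#' flagged excluded.
#'
#' @param reader_times numeric vector of the reader's spike times (s).
#' @param peaks activation peak times (s); at least one.
#' @param half_window_s,bin_ms PETH extent and bin width.
#' @param min_spikes exclusion floor on the total spike count (default 30).
#' @return An object of class `peth_result`: `M` (trials x bins), `m`,
#'   `delays_ms` (bin centers), `n_spikes_total`, `excluded`, plus empty
#'   band fields filled by [shuffle_bands()].
#' @export
compute_peth <- function(reader_times, peaks, half_window_s = 1, bin_ms = 10,
                         min_spikes = 30) {
  if (!length(peaks)) stop("zero activation peaks")
  b <- bin_ms / 1000
  q <- round(2 * half_window_s / b)
  reader_times <- sort(reader_times)
  M <- matrix(0L, nrow = length(peaks), ncol = q)
  for (i in seq_along(peaks)) {
    lo <- peaks[i] - half_window_s
    j1 <- findInterval(lo, reader_times) + 1
    j2 <- findInterval(peaks[i] + half_window_s, reader_times)
    if (j2 >= j1) {
      ix <- floor((reader_times[j1:j2] - lo) / b) + 1
      ix <- ix[ix >= 1 & ix <= q]
      M[i, ] <- tabulate(ix, nbins = q)
    }
  }
  m <- colSums(M)
  centers_ms <- (seq_len(q) - 0.5) * bin_ms - half_window_s * 1000
  structure(list(M = M, m = m, delays_ms = centers_ms,
                 bin_ms = bin_ms, half_window_s = half_window_s,
                 n_spikes_total = sum(M), excluded = sum(M) < min_spikes,
                 shuffle_mean = NULL, shuffle_sd = NULL,
                 pointwise_band = NULL, global_band = NULL,
                 response_score = NULL, n_trials = length(peaks)),
            class = "peth_result")
}

#' @export
print.peth_result <- function(x, ...) {
  cat("peth_result:", x$n_trials, "trials x", length(x$m), "bins,",
      x$n_spikes_total, "spikes", if (x$excluded) "(EXCLUDED)" else "", "\n")
  if (!is.null(x$global_band))
    cat("  global band", signif(x$global_band, 4),
        "| peak m", max(x$m), "at", x$delays_ms[which.max(x$m)], "ms\n")
  invisible(x)
}

# one shuffled PETH: independently permute the time bins within each trial
# row of M. Only occupied bins matter for the column sums: the counts of a
# row land on a uniformly random ordered subset of bin positions.
.null_peth_sums <- function(occ_bins, occ_vals, q) {
  out <- numeric(q)
  for (r in seq_along(occ_bins)) {
    k <- length(occ_bins[[r]])
    pos <- if (k == 1) sample.int(q, 1L) else sample.int(q, k)
    out[pos] <- out[pos] + occ_vals[[r]]
  }
  out
}

#' Monte-Carlo confidence bands for a PETH
#'
#' Null PETHs are built by independently permuting the time bins within
#' each trial row of the response matrix (each trial keeps its spike count;
#' temporal alignment to the event is destroyed). The pointwise band is the
#' per-bin 95th percentile of the null sums; the global band is the 95th
#' percentile of the null maxima over bins, which controls for multiple
#' comparisons across bins. The response score is
#' `(m - shuffle_mean) / shuffle_sd` per bin.
#'
#' @param peth a `peth_result` (not excluded).
#' @param n_shuffles permutation repeats (default 200).
#' @param seed RNG seed.
#' @param level band percentile (default 0.95).
#' @return the `peth_result` with `shuffle_mean`, `shuffle_sd`,
#'   `pointwise_band`, `global_band`, `response_score` filled.
#' @export
shuffle_bands <- function(peth, n_shuffles = 200, seed = 1L, level = 0.95) {
  if (peth$excluded) stop("PETH excluded (fewer spikes than the minimum)")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  q <- ncol(peth$M)
  occ <- apply(peth$M, 1, function(row) which(row > 0), simplify = FALSE)
  nz <- which(lengths(occ) > 0)
  occ_bins <- occ[nz]
  occ_vals <- lapply(nz, function(r) peth$M[r, occ[[r]]])
  null_m <- matrix(0, n_shuffles, q)
  for (s in seq_len(n_shuffles))
    null_m[s, ] <- .null_peth_sums(occ_bins, occ_vals, q)
  peth$shuffle_mean <- colMeans(null_m)
  peth$shuffle_sd <- apply(null_m, 2, stats::sd)
  peth$pointwise_band <- apply(null_m, 2, stats::quantile, probs = level, names = FALSE)
  peth$global_band <- stats::quantile(apply(null_m, 1, max), level, names = FALSE)
  sd_safe <- pmax(peth$shuffle_sd, 1e-12)
  peth$response_score <- (peth$m - peth$shuffle_mean) / sd_safe
  peth
}

#' Classify an assembly-reader pair
#'
#' A pair is significant when (a) the PETH exceeds the pointwise band in at
#' least one bin inside the response window (10-30 ms by default), (b) the
#' PETH maximum exceeds the global band, and (c) the PETH mode (argmax) sits
#' at a positive delay (the reader follows the assembly). The first
#' significant bin inside the window gives the response delay.
#'
#' @param peth a `peth_result` with bands computed.
#' @param response_window_ms two-element window (ms), default `c(10, 30)`.
#' @return list with `testable`, `significant`, `first_sig_delay_ms`,
#'   `mode_delay_ms`, `peak_score`.
#' @export
classify_reader_pair <- function(peth, response_window_ms = c(10, 30)) {
  if (peth$excluded)
    return(list(testable = FALSE, significant = FALSE,
                first_sig_delay_ms = NA_real_, mode_delay_ms = NA_real_,
                peak_score = NA_real_))
  if (is.null(peth$pointwise_band)) stop("bands not computed; run shuffle_bands()")
  d <- peth$delays_ms
  in_win <- d > response_window_ms[1] & d < response_window_ms[2] + peth$bin_ms / 2
  over_pw <- peth$m > peth$pointwise_band
  mode_i <- which.max(peth$m)
  crit_a <- any(over_pw & in_win)
  crit_b <- max(peth$m) > peth$global_band
  crit_c <- d[mode_i] > 0 && sum(peth$m == max(peth$m)) == 1
  sig_bins <- which(over_pw & in_win)
  list(testable = TRUE,
       significant = crit_a && crit_b && crit_c,
       first_sig_delay_ms = if (length(sig_bins)) d[sig_bins[1]] else NA_real_,
       mode_delay_ms = d[mode_i],
       peak_score = if (!is.null(peth$response_score)) max(peth$response_score) else NA_real_)
}

#' Distribution of first-significant delays across pairs
#'
#' For every 10-ms delay bin, the percentage of pairs whose first
#' significant bin falls there (among testable pairs), where a bin is
#' significant when the PETH exceeds both the pointwise and the global band
#' in that bin. Used to find the delay at which significant pairs peak.
#'
#' @param peths list of `peth_result`s with bands computed.
#' @return data.frame (`delay_ms`, `percent`).
#' @export
delay_profile <- function(peths) {
  peths <- peths[!vapply(peths, function(p) p$excluded, logical(1))]
  if (!length(peths)) stop("no testable pairs")
  d <- peths[[1]]$delays_ms
  first <- vapply(peths, function(p) {
    over <- p$m > p$pointwise_band & p$m > p$global_band
    i <- which(over)
    if (length(i)) d[i[1]] else NA_real_
  }, numeric(1))
  tab <- table(factor(first, levels = d))
  data.frame(delay_ms = d, percent = 100 * as.numeric(tab) / length(peths))
}

#' Split-half stability of the response score
#'
#' Partitions activation peaks into two balanced random halves (dealing
#' time chunks, so both halves sample the whole recording), computes the
#' response-score curve in each half, and reports their correlation.
#'
#' @param reader_times reader spike times (s).
#' @param peaks activation peak times (s).
#' @param n_shuffles,seed passed to [shuffle_bands()].
#' @param min_spikes minimum total spikes per half (default 30).
#' @return list with `testable`, `correlation`, `score1`, `score2`.
#' @export
split_half_response_score <- function(reader_times, peaks, n_shuffles = 200,
                                      seed = 1L, min_spikes = 30) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ord <- sample(length(peaks))
  half <- integer(length(peaks)); half[ord] <- rep_len(1:2, length(peaks))
  scores <- vector("list", 2)
  for (h in 1:2) {
    p <- compute_peth(reader_times, peaks[half == h], min_spikes = min_spikes)
    if (p$excluded) return(list(testable = FALSE, correlation = NA_real_,
                                score1 = NULL, score2 = NULL))
    scores[[h]] <- shuffle_bands(p, n_shuffles, seed = seed + h)$response_score
  }
  list(testable = TRUE,
       correlation = stats::cor(scores[[1]], scores[[2]]),
       score1 = scores[[1]], score2 = scores[[2]])
}

# mean reader spike count in (peak + lo, peak + hi] per event
.event_window_counts <- function(reader_times, peaks, lo = 0.010, hi = 0.030) {
  reader_times <- sort(reader_times)
  findInterval(peaks + hi, reader_times) - findInterval(peaks + lo, reader_times)
}

#' Reader response stratified by the number of coactive members
#'
#' Mean 10-30 ms reader response for each stratum of `n_active` (recruited
#' member count), with a Spearman trend statistic computed over events.
#'
#' @param reader_times reader spike times (s).
#' @param events event data.frame from [extract_activation_events()]
#'   (`peak_s`, `n_active`).
#' @param response_window_ms response window (ms).
#' @param min_events strata with fewer events are omitted (default 20).
#' @return list with `strata` (data.frame `n_active`, `mean_response`,
#'   `n_events`), `spearman_rho`, `trend_defined`.
#' @export
member_count_response_curve <- function(reader_times, events,
                                        response_window_ms = c(10, 30),
                                        min_events = 20) {
  cnt <- .event_window_counts(reader_times, events$peak_s,
                              response_window_ms[1] / 1000,
                              response_window_ms[2] / 1000)
  keep_lv <- as.integer(names(which(table(events$n_active) >= min_events)))
  sel <- events$n_active %in% keep_lv
  strata <- do.call(rbind, lapply(sort(keep_lv), function(k)
    data.frame(n_active = k,
               mean_response = mean(cnt[events$n_active == k]),
               n_events = sum(events$n_active == k))))
  if (is.null(strata) || nrow(strata) < 2)
    return(list(strata = strata, spearman_rho = NA_real_, trend_defined = FALSE))
  rho <- suppressWarnings(
    stats::cor(events$n_active[sel], cnt[sel], method = "spearman"))
  list(strata = strata, spearman_rho = rho, trend_defined = TRUE)
}

#' Reader response with the most influential members silent
#'
#' Ranks members by their individual influence on the reader (mean 10-30 ms
#' response following each member's spikes emitted outside activation
#' epochs), then recomputes the mean reader response using only events in
#' which the top-k influencers were not recruited, and compares it to the
#' reader's baseline rate.
#'
#' @param reader_times reader spike times (s).
#' @param events a filled `activation_series`, or an event data.frame with
#'   a `recruited` attribute (e.g. from [find_subset_events()]).
#' @param spikes the `spike_data` (for member trains).
#' @param epochs analysis epochs (for the baseline rate).
#' @param k leave-out count (1 or 2; must be < number of members).
#' @param members member ids (taken from the series if one is passed).
#' @param min_events fewer qualifying events => not testable.
#' @return list with `testable`, `response_rate_hz` (left-out events),
#'   `baseline_rate_hz`, `influence` (named, per member), `n_events`.
#' @export
leave_k_out_response <- function(reader_times, events, spikes, epochs, k = 1,
                                 members = NULL, min_events = 20) {
  if (inherits(events, "activation_series")) {
    members <- events$members
    ev <- events$events
  } else ev <- events
  if (is.null(members)) stop("members required with a plain event table")
  if (k >= length(members)) stop("k must be smaller than the member count")
  recruited <- attr(ev, "recruited")
  # influence: response following member spikes outside activation runs
  influence <- vapply(members, function(u) {
    st <- unit_spikes(spikes, u)
    if (nrow(ev)) {
      inside <- rep(FALSE, length(st))
      for (r in seq_len(nrow(ev)))
        inside <- inside | (st >= ev$start_s[r] & st <= ev$stop_s[r])
      st <- st[!inside]
    }
    if (!length(st)) return(0)
    mean(.event_window_counts(reader_times, st))
  }, numeric(1))
  names(influence) <- members
  top <- members[order(-influence)][seq_len(k)]
  keep <- vapply(recruited, function(r) !any(top %in% r), logical(1))
  if (sum(keep) < min_events)
    return(list(testable = FALSE, response_rate_hz = NA_real_,
                baseline_rate_hz = NA_real_, influence = influence,
                n_events = sum(keep)))
  cnt <- .event_window_counts(reader_times, ev$peak_s[keep])
  win_s <- 0.020
  baseline <- sum(in_intervals(reader_times, epochs)) / interval_duration(epochs)
  list(testable = TRUE,
       response_rate_hz = mean(cnt) / win_s,
       baseline_rate_hz = baseline,
       influence = influence, n_events = sum(keep))
}
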
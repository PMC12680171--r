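# reader spike counts in a bin of width `bin_s` centered at trigger + delay,
# for every (trigger, delay) combination; returns n_trig x n_delay matrix
.delay_counts <- function(reader_times, triggers, delays, bin_s) {
  reader_times <- sort(reader_times)
  left <- outer(triggers, delays, "+") - bin_s / 2
  cnt <- findInterval(left + bin_s, reader_times) - findInterval(left, reader_times)
  matrix(cnt, nrow = length(triggers))
}

# member spike counts in a bin of width `bin_s` centered on each trigger.
# The trigger spike itself is excluded from its own member's count
# (`trig_members`), so the constant term carries the single-spike response
# and the member columns measure co-occurring spikes only.
.member_design <- function(spikes, members, triggers, bin_s, trig_members = NULL) {
  X <- matrix(0, nrow = length(triggers), ncol = length(members))
  for (i in seq_along(members)) {
    st <- unit_spikes(spikes, members[i])
    X[, i] <- findInterval(triggers + bin_s / 2, st) -
      findInterval(triggers - bin_s / 2, st)
    if (!is.null(trig_members))
      X[, i] <- X[, i] - as.integer(trig_members == members[i])
  }
  X[X < 0] <- 0L
  cbind(intercept = 1, X)
}

# split member spikes into in-assembly triggers (inside supra-threshold
# activation runs) and out-of-assembly training triggers (all other member
# spikes, optionally minus extra exclusion intervals).
.split_triggers <- function(spikes, members, series, extra_exclude = NULL) {
  tr <- lapply(members, function(u) unit_spikes(spikes, u))
  st <- unlist(tr)
  uu <- rep(members, lengths(tr))
  o <- order(st); st <- st[o]; uu <- uu[o]
  ev <- series$events
  inside <- rep(FALSE, length(st))
  if (!is.null(ev) && nrow(ev)) {
    iv <- interval_set(ev$start_s, ev$stop_s + 1e-9)
    inside <- in_intervals(st, iv)
  }
  excl <- rep(FALSE, length(st))
  if (!is.null(extra_exclude) && nrow(extra_exclude))
    excl <- in_intervals(st, extra_exclude)
  ki <- inside & !excl
  ko <- !inside & !excl
  list(inside = st[ki], inside_members = uu[ki],
       outside = st[ko], outside_members = uu[ko])
}

#' Linear readout of a reader from individual member spikes
#'
#' For each delay on a grid spanning +/- 1 s, fits a least-squares linear
#' model (identity link) of the reader's spike count at that delay on the
#' member spike-count vector (m members plus a constant) in timescale-width
#' bins around each out-of-assembly member trigger spike. The fitted
#' weights predict what a reader responding to members independently would
#' do; applying them to in-assembly triggers gives the linear-response
#' estimate `eta`.
#'
#' @param reader_times reader spike times (s).
#' @param spikes the `spike_data` (for member trains).
#' @param series a filled `activation_series` of the assembly (defines which
#'   member spikes are inside activations).
#' @param bin_ms count bin width (default 15, the assembly timescale).
#' @param delay_step_ms delay grid step (default 5).
#' @param max_triggers cap on out-/in-assembly trigger counts (uniformly
#'   subsampled, deterministic) to bound the regression size.
#' @param min_out minimum out-of-assembly triggers (default 200).
#' @param extra_exclude optional `interval_set` of epochs to drop entirely
#'   (used by the timescale scan to remove briefer-scale activations).
#' @param ridge ridge penalty used only if the design is rank-deficient.
#' @return An object of class `linear_readout`: `W` ((m+1) x n_delay),
#'   `delays_ms`, `eta` (mean linear prediction per delay over in-assembly
#'   triggers), `r_in`, `r_out` (mean observed counts per trigger),
#'   `normalizer` (`eta` at +20 ms), `S` (supralinearity per delay),
#'   `n_in`, `n_out`.
#' @export
fit_linear_readout <- function(reader_times, spikes, series, bin_ms = 15,
                               delay_step_ms = 5, max_triggers = 4000,
                               min_out = 200, extra_exclude = NULL,
                               ridge = 1e-8) {
  members <- series$members
  bin_s <- bin_ms / 1000
  tr <- .split_triggers(spikes, members, series, extra_exclude)
  if (length(tr$outside) < min_out)
    stop("fewer than ", min_out, " out-of-assembly member trigger spikes")
  sub <- function(n_have, n) if (n_have > n) round(seq(1, n_have, length.out = n)) else seq_len(n_have)
  io <- sub(length(tr$outside), max_triggers)
  ii <- sub(length(tr$inside), max_triggers)
  t_out <- tr$outside[io]; m_out <- tr$outside_members[io]
  t_in <- tr$inside[ii]; m_in <- tr$inside_members[ii]
  delays <- seq(-1, 1, by = delay_step_ms / 1000)
  X_out <- .member_design(spikes, members, t_out, bin_s, m_out)
  Y_out <- .delay_counts(reader_times, t_out, delays, bin_s)
  XtX <- crossprod(X_out)
  W <- tryCatch(solve(XtX, crossprod(X_out, Y_out)),
                error = function(e) {
                  message("rank-deficient design; ridge fallback (penalty ", ridge, ")")
                  solve(XtX + ridge * diag(nrow(XtX)), crossprod(X_out, Y_out))
                })
  eta <- r_in <- rep(NA_real_, length(delays))
  n_in <- length(t_in)
  if (n_in) {
    X_in <- .member_design(spikes, members, t_in, bin_s, m_in)
    eta <- colMeans(X_in %*% W)
    r_in <- colMeans(.delay_counts(reader_times, t_in, delays, bin_s))
  }
  i20 <- which.min(abs(delays - 0.020))
  normalizer <- eta[i20]
  S <- if (is.finite(normalizer) && normalizer > 0) (r_in - eta) / normalizer
       else rep(NA_real_, length(delays))
  structure(list(W = W, delays_ms = delays * 1000, eta = eta,
                 r_in = r_in, r_out = colMeans(Y_out),
                 normalizer = normalizer, S = S,
                 n_in = n_in, n_out = length(t_out), bin_ms = bin_ms,
                 triggers_in = t_in, trigger_members_in = m_in,
                 triggers_out = t_out, trigger_members_out = m_out,
                 members = members),
            class = "linear_readout")
}

#' Supralinearity index per delay
#'
#' `S(dt) = (mean observed in-assembly response - mean linear prediction) /
#' eta(20 ms)`. Zero everywhere for a reader whose in-assembly responses
#' equal the linear prediction; positive around +20 ms for a collective
#' reader. Not testable when the 20-ms normalizer is non-positive.
#'
#' @param readout a `linear_readout` from [fit_linear_readout()].
#' @return list with `testable`, `S` (per delay), `delays_ms`, `S20`
#'   (at +20 ms), `S_baseline` (at -500 ms).
#' @export
supralinearity_index <- function(readout) {
  if (!is.finite(readout$normalizer) || readout$normalizer <= 0)
    return(list(testable = FALSE, S = NULL, delays_ms = readout$delays_ms,
                S20 = NA_real_, S_baseline = NA_real_))
  S <- (readout$r_in - readout$eta) / readout$normalizer
  d <- readout$delays_ms
  list(testable = TRUE, S = S, delays_ms = d,
       S20 = S[which.min(abs(d - 20))],
       S_baseline = S[which.min(abs(d + 500))])
}

#' Simulated "perfect" collective reader
#'
#' Emits exactly one spike 20 ms after each activation event that recruited
#' at least half the assembly members. For large assemblies whose largest
#' observed coactive subset `n` is smaller than the full member count, the
#' half-rule uses `n/2` instead.
#'
#' @param series a filled `activation_series` (events carry recruited sets).
#' @param delay_s spike delay after the event peak (default 0.020).
#' @return numeric vector of surrogate spike times.
#' @export
simulate_perfect_reader <- function(series, delay_s = 0.020) {
  ev <- series$events
  if (is.null(ev) || !nrow(ev)) return(numeric(0))
  n_members <- length(series$members)
  largest <- max(ev$n_active)
  n_eff <- if (largest < n_members) largest else n_members
  sort(ev$peak_s[ev$n_active >= n_eff / 2] + delay_s)
}

#' Simulated "independent" reader
#'
#' Fires 20 ms after every spike emitted by any assembly member, regardless
#' of collective activity: the exact copy of the pooled member trains
#' shifted by +20 ms.
#'
#' @param spikes a `spike_data` object.
#' @param members member unit ids.
#' @param delay_s shift (default 0.020).
#' @return numeric vector of surrogate spike times.
#' @export
simulate_independent_reader <- function(spikes, members, delay_s = 0.020) {
  sort(unlist(lapply(members, function(u) unit_spikes(spikes, u)))) + delay_s
}

#' Supralinearity across detection timescales
#'
#' Re-detects assemblies at each timescale, matches the reference assembly
#' across scales by absolute cosine (>= 0.7), excludes epochs containing
#' activations of the same assembly at briefer scales in the scan (so each
#' scale only uses activity specifically expressed at that scale), and
#' recomputes the supralinearity curve. The observed and linear-prediction
#' curves are concatenated into a single vector for z-scoring before taking
#' their difference, so scales are comparable.
#'
#' @param spikes,epochs recording and analysis epochs.
#' @param reader_unit unit id of the reader.
#' @param ref_assembly an `assembly_model` detected at the reference scale
#'   (its activations at briefer scales drive the exclusion rule).
#' @param scales_ms detection bin widths to scan (ascending).
#' @param ... passed to [fit_linear_readout()].
#' @return data.frame (`scale_ms`, `matched`, `testable`, `S20_z`,
#'   `S_baseline_z`, `n_in`, `n_events`): `S20_z` is the observed-minus-
#'   linear difference at +20 ms after conjoint z-scoring.
#' @export
timescale_scan <- function(spikes, epochs, reader_unit, ref_assembly,
                           scales_ms = c(15, 25, 50), ...) {
  scales_ms <- sort(scales_ms)
  reader_times <- unit_spikes(spikes, reader_unit)
  briefer_runs <- NULL   # accumulated activation runs at briefer scales
  rows <- list()
  for (s in scales_ms) {
    Z <- bin_and_zscore(spikes, epochs, bin_width_ms = s)
    det <- filter_mixed_sign(detect_assemblies(Z))$kept
    m <- .match_assemblies(list(ref_assembly), det)
    if (!nrow(m)) {
      rows[[length(rows) + 1]] <- data.frame(scale_ms = s, matched = FALSE,
        testable = FALSE, S20_z = NA_real_, S_baseline_z = NA_real_,
        n_in = 0L, n_events = 0L)
      next
    }
    a <- det[[m$j[1]]]
    ser <- extract_activation_events(
      activation_strength(spikes, a, epochs, window_ms = s, step_ms = 1),
      spikes)
    ev <- ser$events
    excl <- briefer_runs
    # grow the exclusion set for coarser scales
    if (nrow(ev)) {
      new_runs <- data.frame(start = ev$start_s - s / 1000, stop = ev$stop_s + s / 1000)
      briefer_runs <- rbind(briefer_runs, new_runs)
    }
    excl_iv <- NULL
    if (!is.null(excl) && nrow(excl)) {
      o <- order(excl$start)
      st <- excl$start[o]; en <- excl$stop[o]
      merged_s <- st[1]; merged_e <- en[1]
      for (i in seq_along(st)[-1]) {
        if (st[i] <= merged_e[length(merged_e)]) {
          merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], en[i])
        } else { merged_s <- c(merged_s, st[i]); merged_e <- c(merged_e, en[i]) }
      }
      excl_iv <- interval_set(merged_s, merged_e)
    }
    res <- tryCatch({
      ro <- fit_linear_readout(reader_times, spikes, ser, bin_ms = s,
                               extra_exclude = excl_iv, ...)
      both <- c(ro$r_in, ro$eta)
      mu <- mean(both); sg <- max(stats::sd(both), 1e-12)
      diff_z <- (ro$r_in - mu) / sg - (ro$eta - mu) / sg
      d <- ro$delays_ms
      data.frame(scale_ms = s, matched = TRUE, testable = TRUE,
                 S20_z = diff_z[which.min(abs(d - 20))],
                 S_baseline_z = diff_z[which.min(abs(d + 500))],
                 n_in = ro$n_in, n_events = nrow(ev))
    }, error = function(e)
      data.frame(scale_ms = s, matched = TRUE, testable = FALSE,
                 S20_z = NA_real_, S_baseline_z = NA_real_,
                 n_in = 0L, n_events = nrow(ev)))
    rows[[length(rows) + 1]] <- res
  }
  do.call(rbind, rows)
}

#' Find AB and AA two-spike events for a member pair
#'
#' AB events are an A spike followed by a B spike within the timescale,
#' with no intervening A or B spike (the two spikes must be consecutive in
#' the merged train); AA events are two consecutive A spikes under the same
#' rule. Events are disjoint: pairing scans left to right and a spike
#' consumed by one event cannot seed the next (so in A(0), A(8 ms),
#' B(12 ms) the AA pair is found and the A(8)-B(12) pair is rejected). The
#' reference time of an event is the midpoint of its two spikes. With
#' `delay_range` set, the inter-spike interval must fall inside `(lo, hi]`
#' (seconds) instead of `(0, timescale]` — used to stratify by delay at
#' 5-ms precision.
#'
#' @param times_a,times_b spike times (s) of members A and B.
#' @param timescale_ms co-activation window (default 15).
#' @param delay_range optional `c(lo, hi)` in seconds overriding the window.
#' @return list with `ab` and `aa`, each a data.frame (`t_mid`, `dt`).
#' @export
find_ab_aa_events <- function(times_a, times_b, timescale_ms = 15,
                              delay_range = NULL) {
  lo <- 0; hi <- timescale_ms / 1000
  if (!is.null(delay_range)) { lo <- delay_range[1]; hi <- delay_range[2] }
  t <- c(times_a, times_b)
  lab <- c(rep(1L, length(times_a)), rep(2L, length(times_b)))
  o <- order(t); t <- t[o]; lab <- lab[o]
  ab_mid <- ab_dt <- aa_mid <- aa_dt <- numeric(0)
  i <- 1L
  while (i < length(t)) {
    d <- t[i + 1] - t[i]
    if (d > lo && d <= hi && lab[i] == 1L) {
      if (lab[i + 1] == 2L) {
        ab_mid <- c(ab_mid, (t[i] + t[i + 1]) / 2); ab_dt <- c(ab_dt, d)
      } else {
        aa_mid <- c(aa_mid, (t[i] + t[i + 1]) / 2); aa_dt <- c(aa_dt, d)
      }
      i <- i + 2L
    } else i <- i + 1L
  }
  list(ab = data.frame(t_mid = ab_mid, dt = ab_dt),
       aa = data.frame(t_mid = aa_mid, dt = aa_dt))
}

#' Reader response to AB versus AA events
#'
#' Reader PETHs around AB and AA event midpoints, normalized conjointly:
#' the two PETHs are concatenated to compute a single mean and sd, and each
#' is z-scored with those. The difference AB - AA isolates sensitivity to
#' member identity: a coincidence detector responds more to two different
#' members than to two spikes of the same member, an aggregate-rate reader
#' responds equally.
#'
#' @param reader_times reader spike times (s).
#' @param ab_mid,aa_mid event midpoint times (>= `min_events` each).
#' @param half_window_s,bin_ms PETH extent and bin width.
#' @param response_window_ms window (ms) summarized by `diff_response`.
#' @param min_events per-type floor (default 20).
#' @return An object of class `ab_aa_result`: `z_ab`, `z_aa`, `diff`,
#'   `delays_ms`, `diff_response` (mean difference in the response window),
#'   `n_ab`, `n_aa`, `testable`.
#' @export
ab_aa_response <- function(reader_times, ab_mid, aa_mid, half_window_s = 0.5,
                           bin_ms = 10, response_window_ms = c(10, 30),
                           min_events = 20) {
  if (length(ab_mid) < min_events || length(aa_mid) < min_events)
    return(structure(list(testable = FALSE, n_ab = length(ab_mid),
                          n_aa = length(aa_mid)), class = "ab_aa_result"))
  p_ab <- compute_peth(reader_times, ab_mid, half_window_s, bin_ms, min_spikes = 0)
  p_aa <- compute_peth(reader_times, aa_mid, half_window_s, bin_ms, min_spikes = 0)
  m_ab <- p_ab$m / length(ab_mid)   # per-event rate so counts are comparable
  m_aa <- p_aa$m / length(aa_mid)
  both <- c(m_ab, m_aa)
  mu <- mean(both); sg <- stats::sd(both)
  if (!is.finite(sg) || sg == 0)
    return(structure(list(testable = FALSE, n_ab = length(ab_mid),
                          n_aa = length(aa_mid)), class = "ab_aa_result"))
  z_ab <- (m_ab - mu) / sg; z_aa <- (m_aa - mu) / sg
  d <- p_ab$delays_ms
  win <- d > response_window_ms[1] & d < response_window_ms[2] + bin_ms / 2
  structure(list(testable = TRUE, z_ab = z_ab, z_aa = z_aa,
                 diff = z_ab - z_aa, delays_ms = d,
                 diff_response = mean(z_ab[win] - z_aa[win]),
                 n_ab = length(ab_mid), n_aa = length(aa_mid)),
            class = "ab_aa_result")
}
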
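#' Member-combination events from co-firing clusters
#'
#' Finds every moment a distinct combination of assembly members fired
#' together: member spikes are merged and split into maximal clusters in
#' which consecutive spikes are separated by at most the assembly
#' timescale. Each cluster is one event; its combination is the set of
#' distinct members spiking in it (single isolated spikes give the
#' single-member combinations) and its reference time is the mean of its
#' spike times. Unlike threshold-crossing activation events, this covers
#' all possible combinations down to one member, which the pattern
#' completion analysis needs.
#'
#' @param spikes a `spike_data` object.
#' @param members member unit ids.
#' @param timescale_ms clustering timescale (default 15).
#' @return event data.frame (`start_s`, `stop_s`, `peak_s`, `n_active`)
#'   with attribute `recruited` (list of member-id vectors), compatible
#'   with the event consumers.
#' @export
find_subset_events <- function(spikes, members, timescale_ms = 15) {
  ts <- timescale_ms / 1000
  t <- unlist(lapply(members, function(u) unit_spikes(spikes, u)))
  u <- rep(members, vapply(members, function(m) length(unit_spikes(spikes, m)), integer(1)))
  o <- order(t); t <- t[o]; u <- u[o]
  if (!length(t)) {
    ev <- data.frame(start_s = numeric(0), stop_s = numeric(0),
                     peak_s = numeric(0), n_active = integer(0))
    attr(ev, "recruited") <- list()
    return(ev)
  }
  cl <- cumsum(c(1L, as.integer(diff(t) > ts)))
  recruited <- lapply(split(u, cl), function(x) sort(unique(x)))
  t_by <- split(t, cl)
  ev <- data.frame(start_s = vapply(t_by, min, numeric(1)),
                   stop_s = vapply(t_by, max, numeric(1)),
                   peak_s = vapply(t_by, mean, numeric(1)),
                   n_active = vapply(recruited, length, integer(1)))
  rownames(ev) <- NULL
  attr(ev, "recruited") <- unname(recruited)
  ev
}

#' Reader responses per recruited member subset
#'
#' Groups events by their exact recruited member subset and computes the
#' mean 10-30 ms reader response of each subset, expressed as a ratio to
#' the reader's baseline rate over the analysis epochs (a reader at pure
#' baseline gives ratios near 1). Subsets with fewer than `min_events`
#' events are omitted. Events typically come from [find_subset_events()]
#' (all combinations, including partial ones); threshold-crossing events
#' from [extract_activation_events()] are accepted too.
#'
#' @param reader_times reader spike times (s).
#' @param events event data.frame carrying a `recruited` attribute, or a
#'   filled `activation_series`.
#' @param n_members total member count of the assembly (defines the active
#'   fraction); taken from the series if one is passed.
#' @param epochs analysis epochs (baseline rate denominator).
#' @param response_window_ms response window (ms).
#' @param min_events per-subset floor (default 20).
#' @return list with `testable` and `subsets`: data.frame (`subset`
#'   (comma-joined ids), `n_active`, `x` (active fraction), `response`
#'   (baseline ratio), `n_events`), plus `baseline_rate_hz`, `n_members`.
#' @export
subset_responses <- function(reader_times, events, epochs, n_members = NULL,
                             response_window_ms = c(10, 30), min_events = 20) {
  if (inherits(events, "activation_series")) {
    n_members <- length(events$members)
    events <- events$events
  }
  ev <- events
  recruited <- attr(ev, "recruited")
  if (is.null(ev) || !nrow(ev)) return(list(testable = FALSE, subsets = NULL))
  if (is.null(n_members)) n_members <- length(unique(unlist(recruited)))
  key <- vapply(recruited, function(r) paste(sort(r), collapse = ","), character(1))
  cnt <- .event_window_counts(reader_times, ev$peak_s,
                              response_window_ms[1] / 1000,
                              response_window_ms[2] / 1000)
  win_s <- diff(response_window_ms) / 1000
  baseline <- sum(in_intervals(reader_times, epochs)) / interval_duration(epochs)
  if (baseline <= 0) return(list(testable = FALSE, subsets = NULL))
  tab <- table(key)
  keep <- names(tab)[tab >= min_events]
  if (!length(keep)) return(list(testable = FALSE, subsets = NULL))
  rows <- lapply(keep, function(k) {
    sel <- key == k
    n_act <- length(strsplit(k, ",")[[1]])
    data.frame(subset = k, n_active = n_act, x = n_act / n_members,
               response = (mean(cnt[sel]) / win_s) / baseline,
               n_events = sum(sel))
  })
  list(testable = TRUE, subsets = do.call(rbind, rows),
       baseline_rate_hz = baseline, n_members = n_members)
}

#' Sigmoid versus proportional fit of subset responses
#'
#' Responses are normalized by the response to the complete assembly (or
#' the largest observed subset), so the sigmoid
#' `F(x) = 1 / (1 + exp(-k (x - x0)))` and the parameter-free proportional
#' model `F(x) = x` live on the same scale. The sigmoid is fit by bounded
#' least squares (`k` in (0, 100], `x0` in [0, 1], multistart). Both
#' R-squared values use the usual 1 - SSE/SST form; the boost is the excess
#' of each normalized response over the proportional prediction, summarized
#' in tertiles of the active fraction.
#'
#' @param subsets the `subsets` data.frame from [subset_responses()]
#'   (needs >= 4 distinct `x` values).
#' @return An object of class `completion_fit`: `k`, `x0`, `r2_sigmoid`,
#'   `r2_proportional`, `boost` (per observation), `tertile` (1-3 per
#'   observation), `tertile_boost` (named means), `converged`, `data`.
#' @export
fit_sigmoid_vs_proportional <- function(subsets) {
  stopifnot(is.data.frame(subsets))
  if (length(unique(subsets$x)) < 4)
    stop("need >= 4 distinct active fractions to fit")
  x <- subsets$x
  r_complete <- subsets$response[which.max(x)]
  if (r_complete <= 0) stop("non-positive complete-assembly response")
  y <- subsets$response / r_complete
  sse <- function(par) sum((y - stats::plogis(par[1] * (x - par[2])))^2)
  best <- NULL
  for (k0 in c(2, 10, 30)) for (x00 in c(0.3, 0.5, 0.7)) {
    fit <- tryCatch(stats::optim(c(k0, x00), sse, method = "L-BFGS-B",
                                 lower = c(1e-3, 0), upper = c(100, 1)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(structure(list(converged = FALSE), class = "completion_fit"))
  k <- best$par[1]; x0 <- best$par[2]
  sst <- sum((y - mean(y))^2)
  r2_sig <- 1 - best$value / sst
  r2_prop <- 1 - sum((y - x)^2) / sst
  boost <- y - x
  tert <- cut(x, breaks = c(0, 1 / 3, 2 / 3, 1), labels = FALSE)
  tb <- tapply(boost, factor(tert, levels = 1:3), mean)
  structure(list(k = k, x0 = x0, r2_sigmoid = r2_sig,
                 r2_proportional = r2_prop, boost = boost, tertile = tert,
                 tertile_boost = tb, converged = TRUE,
                 data = data.frame(x = x, y = y)),
            class = "completion_fit")
}

#' @export
print.completion_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) { cat("completion_fit: not converged\n"); return(invisible(x)) }
  cat("completion_fit: k =", signif(x$k, 3), "x0 =", signif(x$x0, 3),
      "| R2 sigmoid", signif(x$r2_sigmoid, 3),
      "vs proportional", signif(x$r2_proportional, 3), "\n")
  invisible(x)
}

#' Hoyer coefficient of sparsity
#'
#' `H = (sqrt(n) - sum(r) / sqrt(sum(r^2))) / (sqrt(n) - 1)`: 0 for a
#' uniform positive vector, 1 for a one-hot vector. Scale-invariant.
#'
#' @param r nonnegative response vector over n >= 2 assemblies, not all zero.
#' @return H in [0, 1].
#' @export
hoyer_sparsity <- function(r) {
  n <- length(r)
  if (n < 2) stop("not testable: need >= 2 assemblies")
  if (all(r == 0)) stop("not testable: all responses zero")
  if (any(r < 0)) stop("responses must be nonnegative")
  (sqrt(n) - sum(r) / sqrt(sum(r^2))) / (sqrt(n) - 1)
}

# per-assembly baseline-subtracted (floored) response rates + the pooled
# activation-level counts needed for identity shuffles
.assembly_responses <- function(reader_times, peaks_list, epochs,
                                response_window_ms = c(10, 30)) {
  lo <- response_window_ms[1] / 1000; hi <- response_window_ms[2] / 1000
  win_s <- hi - lo
  baseline <- sum(in_intervals(reader_times, epochs)) / interval_duration(epochs)
  counts <- lapply(peaks_list, function(p) .event_window_counts(reader_times, p, lo, hi))
  r <- vapply(counts, function(cn) max(0, mean(cn) / win_s - baseline), numeric(1))
  list(r = r, counts = counts, baseline = baseline, win_s = win_s)
}

#' Sparsity increase of a unit's assembly responses over an identity shuffle
#'
#' The unit's per-assembly responses (baseline-subtracted 10-30 ms rates,
#' floored at zero) give an observed Hoyer sparsity H. The null H0 is the
#' mean sparsity over shuffles where assembly identities are permuted
#' across all pooled activations (each activation keeps its response but is
#' reassigned to a random assembly, preserving per-assembly activation
#' counts). The increase is `(H - H0) / H0`: near 0 for a unit driven
#' equally by all assemblies, positive for a selective reader.
#'
#' @param reader_times unit spike times (s).
#' @param peaks_list list (one per simultaneously recorded assembly, >= 2)
#'   of activation peak times.
#' @param epochs analysis epochs.
#' @param n_shuffles identity shuffles (default 1000).
#' @param seed RNG seed.
#' @return list with `testable`, `H`, `H0`, `increase`, `responses`.
#' @export
sparsity_increase <- function(reader_times, peaks_list, epochs,
                              n_shuffles = 1000, seed = 1L) {
  stopifnot(length(peaks_list) >= 2)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ar <- .assembly_responses(reader_times, peaks_list, epochs)
  if (all(ar$r == 0)) return(list(testable = FALSE, H = NA_real_,
                                  H0 = NA_real_, increase = NA_real_,
                                  responses = ar$r))
  H <- hoyer_sparsity(ar$r)
  pooled <- unlist(ar$counts)
  sizes <- lengths(ar$counts)
  grp <- rep(seq_along(sizes), sizes)
  n <- length(pooled)
  H0s <- vapply(seq_len(n_shuffles), function(s) {
    perm <- pooled[sample.int(n)]
    means <- vapply(split(perm, grp), mean, numeric(1))
    r0 <- pmax(0, means / ar$win_s - ar$baseline)
    if (all(r0 == 0)) return(NA_real_)
    hoyer_sparsity(r0)
  }, numeric(1))
  H0 <- mean(H0s, na.rm = TRUE)
  if (!is.finite(H0) || H0 == 0)
    return(list(testable = FALSE, H = H, H0 = H0, increase = NA_real_,
                responses = ar$r))
  list(testable = TRUE, H = H, H0 = H0, increase = (H - H0) / H0,
       responses = ar$r)
}

#' Do two assemblies overlap enough for the separation test?
#'
#' Shared members must amount to at least `min_frac` of each assembly's
#' member count, and each assembly must have more than 2 members.
#'
#' @param members1,members2 member id vectors.
#' @param min_frac overlap fraction (default 0.25).
#' @return logical.
#' @export
assemblies_overlap <- function(members1, members2, min_frac = 0.25) {
  shared <- length(intersect(members1, members2))
  length(members1) > 2 && length(members2) > 2 &&
    shared >= min_frac * length(members1) &&
    shared >= min_frac * length(members2)
}

#' Discrimination index between a paired and an overlapping assembly
#'
#' `d = (r1 - r2) / (r1 + r2)` where r1 is the reader's response to its
#' paired assembly and r2 its response to the overlapping assembly
#' (baseline-subtracted, floored 10-30 ms rates). The null distribution
#' comes from pooling the two assemblies' activations and shuffling the
#' labels; the pair separates patterns when the observed d exceeds the 95th
#' percentile of the shuffles.
#'
#' @param reader_times reader spike times (s).
#' @param peaks1,peaks2 activation peaks of the paired and overlapping
#'   assembly (>= `min_events` each).
#' @param epochs analysis epochs.
#' @param n_shuffles label shuffles (default 1000).
#' @param seed RNG seed.
#' @param min_events per-assembly activation floor (default 20).
#' @return list with `testable`, `d`, `null95`, `significant`, `r1`, `r2`,
#'   `null` (the shuffle distribution).
#' @export
discrimination_index <- function(reader_times, peaks1, peaks2, epochs,
                                 n_shuffles = 1000, seed = 1L, min_events = 20) {
  if (length(peaks1) < min_events || length(peaks2) < min_events)
    return(list(testable = FALSE, d = NA_real_, null95 = NA_real_,
                significant = FALSE, r1 = NA_real_, r2 = NA_real_, null = NULL))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ar <- .assembly_responses(reader_times, list(peaks1, peaks2), epochs)
  r1 <- ar$r[1]; r2 <- ar$r[2]
  if (r1 + r2 == 0)
    return(list(testable = FALSE, d = NA_real_, null95 = NA_real_,
                significant = FALSE, r1 = r1, r2 = r2, null = NULL))
  d <- (r1 - r2) / (r1 + r2)
  pooled <- unlist(ar$counts)
  n1 <- length(peaks1); n <- length(pooled)
  null <- vapply(seq_len(n_shuffles), function(s) {
    ix <- sample.int(n, n1)
    m1 <- max(0, mean(pooled[ix]) / ar$win_s - ar$baseline)
    m2 <- max(0, mean(pooled[-ix]) / ar$win_s - ar$baseline)
    if (m1 + m2 == 0) return(0)
    (m1 - m2) / (m1 + m2)
  }, numeric(1))
  null95 <- stats::quantile(null, 0.95, names = FALSE)
  list(testable = TRUE, d = d, null95 = null95, significant = d > null95,
       r1 = r1, r2 = r2, null = null)
}
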
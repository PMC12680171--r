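#' Instantaneous assembly activation strength
#'
#' Member-only quadratic form `A(t) = z(t)' P z(t)` where `P` is the outer
#' product of the assembly weight vector restricted to member rows/columns
#' with the diagonal set to zero (so a burst in a single member contributes
#' nothing), and `z(t)` are the members' sliding-window standardized counts
#' ([sliding_counts()], 15-ms windows stepped by 1 ms by default).
#'
#' @param spikes a `spike_data` object (ideally already epoch-restricted).
#' @param assembly an `assembly_model` with at least two members.
#' @param epochs an `interval_set`.
#' @param window_ms,step_ms sliding-window parameters; `window_ms` defaults
#'   to the assembly's detection timescale.
#' @return An object of class `activation_series`: list with `strength`,
#'   `time` (window centers, s), `window`, `step` (s), `members`, `weights`
#'   (member weights), plus empty `events` (see
#'   [extract_activation_events()]).
#' @export
activation_strength <- function(spikes, assembly, epochs,
                                window_ms = assembly$timescale_ms, step_ms = 1) {
  members <- assembly$members
  if (length(members) < 2) stop("activation strength needs >= 2 members")
  w <- assembly$weights[as.character(members)]
  zc <- sliding_counts(spikes, members, epochs, window_ms, step_ms)
  Zm <- zc$values
  # z' (ww' - diag(w^2)) z = (w.z)^2 - sum(w^2 z^2), members only
  proj <- as.vector(crossprod(w, Zm))
  strength <- proj^2 - colSums((w * Zm)^2)
  structure(list(strength = strength,
                 time = zc$bin_starts + zc$bin_width / 2,
                 window = zc$bin_width, step = step_ms / 1000,
                 members = members, weights = w,
                 baseline = NA_real_, threshold = NA_real_, events = NULL),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  cat("activation_series:", length(x$strength), "samples,",
      length(x$members), "members")
  if (!is.null(x$events)) cat(",", nrow(x$events), "events (threshold",
                              signif(x$threshold, 4), ")")
  cat("\n")
  invisible(x)
}

#' Extract activation events from a strength trace
#'
#' Baseline is the median of the strength trace (a point mass at the
#' empty-window value); the activation threshold is the 95th percentile of
#' the strictly-above-baseline values. Events are maximal contiguous
#' supra-threshold runs; each event's peak is the midpoint of its run, and
#' its recruited members are the members with at least one spike within
#' half a window of the peak.
#'
#' @param series an `activation_series` from [activation_strength()].
#' @param spikes the `spike_data` used to attribute recruited members.
#' @param percentile threshold percentile of above-baseline values
#'   (default 95).
#' @return the series with `baseline`, `threshold` and `events` filled;
#'   `events` is a data.frame (`start_s`, `stop_s`, `peak_s`, `n_active`)
#'   with a list attribute `recruited` of member-id vectors.
#' @export
extract_activation_events <- function(series, spikes, percentile = 95) {
  A <- series$strength
  baseline <- stats::median(A)
  above <- A[A > baseline]
  if (!length(above)) {
    warning("constant strength trace: no events")
    series$baseline <- baseline; series$threshold <- baseline
    series$events <- data.frame(start_s = numeric(0), stop_s = numeric(0),
                                peak_s = numeric(0), n_active = integer(0))
    attr(series$events, "recruited") <- list()
    return(series)
  }
  thr <- stats::quantile(above, percentile / 100, names = FALSE)
  up <- A > thr
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  # drop runs that span a gap between epochs (non-contiguous window centers)
  t <- series$time
  ev <- lapply(sel, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 > i0 && any(diff(t[i0:i1]) > series$step * 1.5)) return(NULL)
    c(t[i0], t[i1])
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev)) ev <- matrix(numeric(0), 0, 2)
  peak <- (ev[, 1] + ev[, 2]) / 2
  half <- series$window / 2
  mem_tr <- lapply(series$members, function(u) unit_spikes(spikes, u))
  recruited <- lapply(peak, function(p) {
    act <- vapply(mem_tr, function(st) {
      i <- findInterval(p + half, st) - findInterval(p - half, st)
      i > 0
    }, logical(1))
    series$members[act]
  })
  series$baseline <- baseline
  series$threshold <- thr
  series$events <- data.frame(start_s = ev[, 1], stop_s = ev[, 2],
                              peak_s = peak,
                              n_active = vapply(recruited, length, integer(1)))
  attr(series$events, "recruited") <- recruited
  series
}

#' Member-only versus all-units activation strength
#'
#' Recomputes the activation strength using the z traces of all units and
#' the full zero-diagonal weight outer product, extracts events from both
#' variants, and reports the fraction of members coactive around each
#' event's peak. The member-only variant is expected to yield events with
#' greater member coactivity: all-units strength can peak when high-rate
#' nonmembers fire without the members.
#'
#' @param spikes,assembly,epochs as in [activation_strength()].
#' @param step_ms sliding step (ms).
#' @return list with `member_only` and `all_units`, each containing the
#'   filled `activation_series` and `coactive_fraction` (mean fraction of
#'   members with a spike around detected peaks).
#' @export
compare_member_vs_all_strength <- function(spikes, assembly, epochs, step_ms = 1) {
  if (length(assembly$members) < 2) stop("needs >= 2 members")
  nonmembers <- setdiff(as.integer(names(assembly$weights)), assembly$members)
  if (!length(nonmembers)) stop("needs >= 1 nonmember")
  ser_m <- extract_activation_events(
    activation_strength(spikes, assembly, epochs, step_ms = step_ms), spikes)
  # all-units variant: same quadratic form over the full weight vector
  all_units <- as.integer(names(assembly$weights))
  fake <- assembly
  fake$members <- all_units
  ser_a <- extract_activation_events(
    activation_strength(spikes, fake, epochs, step_ms = step_ms), spikes)
  frac <- function(ser) {
    if (!nrow(ser$events)) return(NA_real_)
    half <- ser$window / 2
    mem_tr <- lapply(assembly$members, function(u) unit_spikes(spikes, u))
    f <- vapply(ser$events$peak_s, function(p)
      mean(vapply(mem_tr, function(st)
        findInterval(p + half, st) > findInterval(p - half, st), logical(1))),
      numeric(1))
    mean(f)
  }
  list(member_only = list(series = ser_m, coactive_fraction = frac(ser_m)),
       all_units = list(series = ser_a, coactive_fraction = frac(ser_a)))
}
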
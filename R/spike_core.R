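#' Spike-train container
#'
#' Bundles per-unit spike times (seconds) with per-unit metadata: the
#' structure the unit was recorded in (two interconnected regions, e.g. "A"
#' and "B"), and session/animal labels. Spike times are stored sorted within
#' unit; duplicate (unit, time) pairs are dropped.
#'
#' @param unit integer vector, one entry per spike.
#' @param time numeric vector of spike times in seconds, same length as `unit`.
#' @param structure named character vector (or data.frame column) mapping each
#'   unit id to its structure label. Every spiking unit must be labelled.
#' @param session_id,animal_id scalar labels attached to the whole recording.
#' @return An object of class `spike_data`: list with elements `spikes`
#'   (data.frame `unit`, `time`, sorted by unit then time), `units`
#'   (data.frame `unit`, `structure`), `session_id`, `animal_id`.
#' @export
spike_data <- function(unit, time, structure, session_id = "s1", animal_id = "a1") {
  stopifnot(length(unit) == length(time))
  if (length(time) && any(!is.finite(time))) stop("spike times must be finite")
  if (is.data.frame(structure)) {
    units <- data.frame(unit = as.integer(structure$unit),
                        structure = as.character(structure$structure))
  } else {
    units <- data.frame(unit = as.integer(names(structure)),
                        structure = as.character(structure))
  }
  unit <- as.integer(unit)
  missing_units <- setdiff(unique(unit), units$unit)
  if (length(missing_units))
    stop("units without structure label: ", paste(missing_units, collapse = ", "))
  ord <- order(unit, time)
  sp <- data.frame(unit = unit[ord], time = time[ord])
  dup <- duplicated(sp)
  if (any(dup)) sp <- sp[!dup, , drop = FALSE]
  units <- units[order(units$unit), , drop = FALSE]
  rownames(sp) <- rownames(units) <- NULL
  structure(list(spikes = sp, units = units,
                 session_id = session_id, animal_id = animal_id),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("spike_data:", nrow(x$spikes), "spikes,", nrow(x$units), "units,",
      "structures:", paste(sort(unique(x$units$structure)), collapse = "/"),
      "\nsession", x$session_id, "animal", x$animal_id, "\n")
  invisible(x)
}

#' Spike times of one unit
#' @param spikes a `spike_data` object.
#' @param unit unit id.
#' @return numeric vector of spike times (seconds, sorted).
#' @export
unit_spikes <- function(spikes, unit) {
  spikes$spikes$time[spikes$spikes$unit == unit]
}

#' Set of non-overlapping analysis intervals
#'
#' Half-open intervals `[start, stop)` in seconds, e.g. slow-wave-sleep
#' epochs. Intervals are sorted and must not overlap.
#'
#' @param start,stop numeric vectors of equal length.
#' @return An object of class `interval_set` (data.frame `start`, `stop`).
#' @export
interval_set <- function(start, stop) {
  stopifnot(length(start) == length(stop))
  if (!length(start)) stop("no analysis epochs")
  if (any(!(start < stop))) stop("each interval needs start < stop")
  ord <- order(start)
  start <- start[ord]; stop <- stop[ord]
  if (length(start) > 1 && any(start[-1] < stop[-length(stop)]))
    stop("intervals overlap")
  structure(data.frame(start = start, stop = stop), class = c("interval_set", "data.frame"))
}

#' Total duration covered by an interval set
#' @param epochs an `interval_set`.
#' @return duration in seconds.
#' @export
interval_duration <- function(epochs) sum(epochs$stop - epochs$start)

#' Is each time inside some interval?
#' @param t numeric vector of times (seconds).
#' @param epochs an `interval_set`.
#' @return logical vector; membership uses the half-open convention
#'   `start <= t < stop`.
#' @export
in_intervals <- function(t, epochs) {
  # edges start1 stop1 start2 stop2 ...: odd interval index <=> inside
  edges <- as.vector(rbind(epochs$start, epochs$stop))
  findInterval(t, edges) %% 2L == 1L
}

#' Restrict a recording to analysis epochs
#'
#' Keeps only spikes whose times fall inside one of the epochs (half-open
#' `[start, stop)`). The unit set is preserved even if a unit ends up with an
#' empty train.
#'
#' @param spikes a `spike_data` object.
#' @param epochs an `interval_set`.
#' @return a `spike_data` object.
#' @export
restrict_to_intervals <- function(spikes, epochs) {
  if (is.null(epochs) || !nrow(epochs)) stop("no analysis epochs")
  keep <- in_intervals(spikes$spikes$time, epochs)
  out <- spikes
  out$spikes <- spikes$spikes[keep, , drop = FALSE]
  rownames(out$spikes) <- NULL
  out
}

# bin starts for one epoch: left-aligned, only full bins
.epoch_bin_starts <- function(start, stop, width) {
  n <- floor((stop - start) / width + 1e-9)
  if (n < 1) return(numeric(0))
  start + (seq_len(n) - 1) * width
}

#' Bin spike trains and z-score each unit
#'
#' Spike counts per unit per bin, restricted to epochs. Bins are half-open
#' `[t, t + w)`, left-aligned to each epoch start; epochs are binned
#' independently so no bin spans a gap. Each unit's row is z-scored across
#' the in-epoch bins. Units with zero count variance cannot be z-scored and
#' are excluded (with a warning), as are units below `min_rate_hz`.
#'
#' @param spikes a `spike_data` object.
#' @param epochs an `interval_set`.
#' @param bin_width_ms bin width in milliseconds (default 15).
#' @param min_rate_hz units with a lower in-epoch mean rate are excluded from
#'   detection (default 0.05 Hz); low-rate rows make z-scores unstable.
#' @param zscore if `FALSE`, return raw counts (all units retained).
#' @return An object of class `binned_matrix`: list with `values` (units x
#'   bins), `bin_width` (s), `bin_starts` (s), `zscored`, `units` (row unit
#'   ids), `excluded_units`, `row_means`, `row_sds` (count-scale statistics,
#'   reused by [sliding_counts()]).
#' @export
bin_and_zscore <- function(spikes, epochs, bin_width_ms = 15,
                           min_rate_hz = 0.05, zscore = TRUE) {
  stopifnot(bin_width_ms > 0)
  w <- bin_width_ms / 1000
  starts <- unlist(lapply(seq_len(nrow(epochs)), function(i)
    .epoch_bin_starts(epochs$start[i], epochs$stop[i], w)))
  if (!length(starts)) stop("epochs shorter than one bin")
  units <- spikes$units$unit
  counts <- matrix(0L, nrow = length(units), ncol = length(starts),
                   dimnames = list(units, NULL))
  # count spikes per bin: findInterval into the bin-edge grid of each epoch
  edges <- c(starts, starts[length(starts)] + w)
  for (i in seq_along(units)) {
    st <- unit_spikes(spikes, units[i])
    if (!length(st)) next
    idx <- findInterval(st, edges)
    ok <- idx >= 1 & idx <= length(starts) & st < edges[idx + 1]
    # guard against epoch-tail spikes beyond the last full bin of an epoch
    ok[ok] <- st[ok] - starts[idx[ok]] < w & st[ok] >= starts[idx[ok]]
    if (any(ok)) {
      tab <- tabulate(idx[ok], nbins = length(starts))
      counts[i, ] <- tab
    }
  }
  if (!zscore) {
    return(structure(list(values = counts, bin_width = w, bin_starts = starts,
                          zscored = FALSE, units = units,
                          excluded_units = integer(0),
                          row_means = rowMeans(counts),
                          row_sds = apply(counts, 1, stats::sd)),
                     class = "binned_matrix"))
  }
  mu <- rowMeans(counts)
  sds <- sqrt(rowMeans(counts^2) - mu^2)  # population sd over in-epoch bins
  total_t <- interval_duration(epochs)
  rates <- rowSums(counts) / total_t
  bad <- sds <= 0 | rates < min_rate_hz
  if (any(bad))
    warning(sum(bad), " unit(s) excluded from z-scored matrix (zero variance or < ",
            min_rate_hz, " Hz)")
  keep <- which(!bad)
  Z <- (counts[keep, , drop = FALSE] - mu[keep]) / sds[keep]
  structure(list(values = Z, bin_width = w, bin_starts = starts,
                 zscored = TRUE, units = units[keep],
                 excluded_units = units[bad],
                 row_means = mu[keep], row_sds = sds[keep]),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("binned_matrix:", nrow(x$values), "units x", ncol(x$values), "bins,",
      "bin width", x$bin_width * 1000, "ms,",
      if (x$zscored) "z-scored" else "raw counts", "\n")
  invisible(x)
}

#' Sliding-window member spike counts
#'
#' Overlapping windows of width `window_ms` advanced by `step_ms` within each
#' epoch (no window spans a gap). Rows are standardized with the mean and
#' variance of non-overlapping bins at the same width (the statistics used at
#' detection time), so the resulting z traces are on the scale of the
#' detection matrix.
#'
#' @param spikes a `spike_data` object.
#' @param members unit ids to include (non-empty).
#' @param epochs an `interval_set`.
#' @param window_ms,step_ms window width and step in milliseconds; `step_ms`
#'   must not exceed `window_ms`.
#' @param standardize z-score rows using matching-width bin statistics.
#' @return a `binned_matrix` (rows = members, bins = sliding windows);
#'   `bin_starts` are window start times.
#' @export
sliding_counts <- function(spikes, members, epochs, window_ms = 15, step_ms = 1,
                           standardize = TRUE) {
  if (!length(members)) stop("empty member set")
  stopifnot(step_ms <= window_ms, step_ms > 0)
  w <- window_ms / 1000; s <- step_ms / 1000
  starts <- unlist(lapply(seq_len(nrow(epochs)), function(i) {
    n <- floor((epochs$stop[i] - epochs$start[i] - w) / s + 1e-9) + 1
    if (n < 1) return(numeric(0))
    epochs$start[i] + (seq_len(n) - 1) * s
  }))
  if (!length(starts)) stop("epochs shorter than one window")
  vals <- matrix(0, nrow = length(members), ncol = length(starts),
                 dimnames = list(members, NULL))
  for (i in seq_along(members)) {
    st <- unit_spikes(spikes, members[i])
    # count spikes in [t, t+w) for every window start t
    vals[i, ] <- findInterval(starts + w - 1e-12, st) - findInterval(starts - 1e-12, st)
  }
  mu <- sds <- NULL
  if (standardize) {
    base <- bin_and_zscore(spikes, epochs, bin_width_ms = window_ms,
                           min_rate_hz = 0, zscore = FALSE)
    ix <- match(members, base$units)
    mu <- base$row_means[ix]
    m2 <- rowMeans(base$values[ix, , drop = FALSE]^2)
    sds <- sqrt(m2 - mu^2)
    if (any(sds <= 0)) stop("member with zero count variance; cannot standardize")
    vals <- (vals - mu) / sds
  }
  structure(list(values = vals, bin_width = w, bin_starts = starts,
                 zscored = standardize, units = as.integer(members),
                 excluded_units = integer(0), row_means = mu, row_sds = sds,
                 step = s),
            class = "binned_matrix")
}
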
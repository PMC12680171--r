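#' Upper bound of the Marcenko-Pastur eigenvalue distribution
#'
#' For an n_units x n_bins matrix of independent standardized entries, the
#' eigenvalues of the correlation matrix concentrate below
#' `(1 + sqrt(n_units/n_bins))^2`; correlation eigenvalues above this bound
#' signal genuine co-activation structure.
#'
#' @param n_units,n_bins matrix dimensions; requires `n_bins > n_units`.
#' @return the significance threshold on correlation-matrix eigenvalues.
#' @export
marcenko_pastur_bound <- function(n_units, n_bins) {
  if (n_bins <= n_units)
    stop("Marcenko-Pastur upper bound requires more bins than units")
  (1 + sqrt(n_units / n_bins))^2
}

#' Otsu threshold on absolute weights
#'
#' Exhaustive search over thresholds between consecutive sorted `|weights|`
#' maximizing the inter-class variance; the above-threshold group are the
#' assembly members. Effectiveness is the ratio of inter-class to total
#' variance (1 for perfectly bimodal weights).
#'
#' @param weights numeric vector (assembly weight vector); at least two
#'   distinct absolute values.
#' @return list with `threshold` (midpoint between the two groups),
#'   `members` (indices, or names if `weights` is named), `effectiveness`.
#' @export
otsu_members <- function(weights) {
  a <- abs(weights)
  if (length(unique(a)) < 2) stop("no separation: all absolute weights equal")
  s <- sort(a)
  n <- length(s)
  mu_t <- mean(s)
  var_t <- mean((s - mu_t)^2)
  best <- -Inf; best_i <- 1
  for (i in 1:(n - 1)) {
    if (s[i] == s[i + 1]) next
    w1 <- i / n; w2 <- 1 - w1
    mu1 <- mean(s[1:i]); mu2 <- mean(s[(i + 1):n])
    v <- w1 * w2 * (mu1 - mu2)^2
    if (v > best) { best <- v; best_i <- i }
  }
  thr <- (s[best_i] + s[best_i + 1]) / 2
  idx <- which(a > thr)
  members <- if (!is.null(names(weights))) names(weights)[idx] else idx
  list(threshold = thr, members = members, effectiveness = best / var_t)
}

# symmetric fixed-point ICA (logcosh contrast) on a whitened k x T matrix.
# Deterministic: initial unmixing drawn from a local RNG seeded by `seed`.
.fast_ica <- function(X, seed = 42L, max_iter = 400, tol = 1e-8) {
  k <- nrow(X); Tn <- ncol(X)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors) %*% W
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% X
    G <- tanh(WX)
    W1 <- (G %*% t(X)) / Tn - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Detect candidate cell assemblies
#'
#' Eigendecomposes the correlation matrix of the z-scored spike-count matrix,
#' keeps principal components whose eigenvalues exceed the Marcenko-Pastur
#' upper bound, runs fixed-point ICA on the projection of the matrix onto
#' that subspace, scales each component to unit norm with the highest
#' absolute weight positive, and attaches Otsu membership. Components that
#' duplicate one another (`|cosine| > 0.95`) are deduplicated, keeping the
#' one with higher Otsu effectiveness.
#'
#' @param Z a z-scored `binned_matrix` (from [bin_and_zscore()]) with at
#'   least 2 units; a warning is given when there are fewer than 10 bins per
#'   unit.
#' @param ica_seed seed for the deterministic ICA initialization.
#' @return list of `assembly_model` objects (possibly empty). Each has
#'   `weights` (unit-norm named vector over the matrix's units), `members`
#'   (unit ids above the Otsu threshold), `otsu_threshold`, `effectiveness`,
#'   `timescale_ms` (the bin width of `Z`), `sign_valid` (all member weights
#'   share a sign), `id`.
#' @export
detect_assemblies <- function(Z, ica_seed = 42L) {
  stopifnot(inherits(Z, "binned_matrix"), isTRUE(Z$zscored))
  n <- nrow(Z$values); q <- ncol(Z$values)
  if (n < 2) stop("need at least 2 units")
  if (q < 10 * n) warning("fewer than 10x more bins than units; detection may be unstable")
  C <- tcrossprod(Z$values) / q           # correlation matrix (rows are z-scored)
  e <- eigen(C, symmetric = TRUE)
  lambda_max <- marcenko_pastur_bound(n, q)
  sig <- which(e$values > lambda_max)
  if (!length(sig)) return(list())
  k <- length(sig)
  V <- e$vectors[, sig, drop = FALSE]
  d <- e$values[sig]
  # whitened projection onto the significant subspace
  X <- diag(1 / sqrt(d), k) %*% t(V) %*% Z$values
  if (k == 1) {
    A <- V                                  # single component: ICA is moot
  } else {
    W <- .fast_ica(X, seed = ica_seed)
    A <- V %*% diag(sqrt(d), k) %*% t(W)    # mixing columns in unit space
  }
  out <- list()
  for (j in seq_len(ncol(A))) {
    w <- A[, j]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    names(w) <- Z$units
    ot <- otsu_members(w)
    members <- as.integer(ot$members)
    sgn <- sign(w[as.character(members)])
    out[[length(out) + 1]] <- structure(
      list(weights = w, members = members, otsu_threshold = ot$threshold,
           effectiveness = ot$effectiveness,
           timescale_ms = Z$bin_width * 1000,
           sign_valid = all(sgn > 0) || all(sgn < 0),
           id = NA_integer_),
      class = "assembly_model")
  }
  # deduplicate near-identical components
  if (length(out) > 1) {
    keep <- rep(TRUE, length(out))
    for (i in seq_along(out)) {
      if (!keep[i]) next
      for (j in seq_along(out)) {
        if (j <= i || !keep[j]) next
        cs <- abs(sum(out[[i]]$weights * out[[j]]$weights))
        if (cs > 0.95) {
          drop <- if (out[[i]]$effectiveness >= out[[j]]$effectiveness) j else i
          keep[drop] <- FALSE
        }
      }
    }
    out <- out[keep]
  }
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' @export
print.assembly_model <- function(x, ...) {
  cat("assembly_model", x$id, "| timescale", x$timescale_ms, "ms |",
      length(x$members), "members:", paste(x$members, collapse = ","),
      "| effectiveness", round(x$effectiveness, 3),
      if (x$sign_valid) "| same-sign" else "| MIXED-SIGN", "\n")
  invisible(x)
}

#' Discard mixed-sign assemblies
#'
#' Assemblies whose member weights carry both signs do not index coincident
#' firing (high strength can reflect one subgroup active while the other is
#' silent) and typically reflect ICA failures; they are set aside.
#'
#' @param assemblies list of `assembly_model`s.
#' @return list with `kept` (sign_valid) and `discarded`.
#' @export
filter_mixed_sign <- function(assemblies) {
  ok <- vapply(assemblies, function(a) isTRUE(a$sign_valid), logical(1))
  list(kept = assemblies[ok], discarded = assemblies[!ok])
}

#' Shuffle spike identities
#'
#' Randomly permutes unit labels across spikes while preserving each unit's
#' total spike count and leaving all spike times untouched. Global rate
#' fluctuations are preserved by construction; fine-timescale co-activation
#' is destroyed. The canonical negative control for assembly detection.
#'
#' @param spikes a `spike_data` object with at least 2 units.
#' @param seed RNG seed.
#' @return a `spike_data` object.
#' @export
shuffle_spike_identities <- function(spikes, seed = 1L) {
  if (nrow(spikes$units) < 2) stop("need at least 2 units")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  sp <- spikes$spikes
  sp$unit <- sample(sp$unit)
  spike_data(sp$unit, sp$time,
             stats::setNames(spikes$units$structure, spikes$units$unit),
             session_id = spikes$session_id, animal_id = spikes$animal_id)
}

# greedy matching of two assembly lists by maximal |cosine| on shared units
.match_assemblies <- function(as1, as2, threshold = 0.7) {
  if (!length(as1) || !length(as2))
    return(data.frame(i = integer(0), j = integer(0), cosine = numeric(0)))
  cs <- matrix(0, length(as1), length(as2))
  for (i in seq_along(as1)) for (j in seq_along(as2)) {
    u <- intersect(names(as1[[i]]$weights), names(as2[[j]]$weights))
    if (length(u) < 2) next
    w1 <- as1[[i]]$weights[u]; w2 <- as2[[j]]$weights[u]
    cs[i, j] <- abs(sum(w1 * w2)) / sqrt(sum(w1^2) * sum(w2^2))
  }
  res <- data.frame(i = integer(0), j = integer(0), cosine = numeric(0))
  while (TRUE) {
    m <- which.max(cs)
    if (!length(m) || cs[m] < threshold) break
    i <- (m - 1) %% nrow(cs) + 1; j <- (m - 1) %/% nrow(cs) + 1
    res <- rbind(res, data.frame(i = i, j = j, cosine = cs[m]))
    cs[i, ] <- -Inf; cs[, j] <- -Inf
  }
  res
}

#' Split-half cross-validation of assembly detection
#'
#' Partitions the analysis epochs into two balanced sets of random time
#' intervals (fixed-length chunks dealt at random), detects assemblies
#' independently in each half, matches them greedily by maximal absolute
#' cosine, and compares each matched pair's weight correlation to a
#' weight-shuffle null (95th percentile of |cosine| after permuting one
#' vector's entries).
#'
#' @param spikes,epochs recording and analysis epochs.
#' @param bin_width_ms detection bin width.
#' @param chunk_s chunk length used to deal epochs into halves.
#' @param n_null permutations for the weight-shuffle null.
#' @param seed RNG seed.
#' @return list with `matches` (data.frame `i`, `j`, `cosine`,
#'   `null95`, `significant`), `n_half1`, `n_half2`.
#' @export
split_half_crossvalidate <- function(spikes, epochs, bin_width_ms = 15,
                                     chunk_s = 20, n_null = 200, seed = 1L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # chop epochs into chunks and deal them alternately after shuffling
  ch_start <- unlist(lapply(seq_len(nrow(epochs)), function(i)
    seq(epochs$start[i], epochs$stop[i] - chunk_s / 2, by = chunk_s)))
  ch_stop <- unlist(lapply(seq_len(nrow(epochs)), function(i)
    pmin(seq(epochs$start[i], epochs$stop[i] - chunk_s / 2, by = chunk_s) + chunk_s,
         epochs$stop[i])))
  ord <- sample(length(ch_start))
  half_of <- integer(length(ch_start)); half_of[ord] <- rep_len(1:2, length(ord))
  halves <- lapply(1:2, function(h) {
    sel <- which(half_of == h)
    sel <- sel[order(ch_start[sel])]
    interval_set(ch_start[sel], ch_stop[sel])
  })
  det <- lapply(halves, function(ep) {
    Z <- bin_and_zscore(restrict_to_intervals(spikes, ep), ep, bin_width_ms)
    filter_mixed_sign(detect_assemblies(Z))$kept
  })
  m <- .match_assemblies(det[[1]], det[[2]])
  if (nrow(m)) {
    m$null95 <- vapply(seq_len(nrow(m)), function(r) {
      w1 <- det[[1]][[m$i[r]]]$weights
      w2 <- det[[2]][[m$j[r]]]$weights
      u <- intersect(names(w1), names(w2))
      w1 <- w1[u]; w2 <- w2[u]
      null <- replicate(n_null, abs(sum(w1 * sample(w2))) /
                          sqrt(sum(w1^2) * sum(w2^2)))
      stats::quantile(null, 0.95, names = FALSE)
    }, numeric(1))
    m$significant <- m$cosine > m$null95
  }
  list(matches = m, n_half1 = length(det[[1]]), n_half2 = length(det[[2]]))
}

#' Peer-prediction gain of assembly members
#'
#' How well each member's binned activity is predicted by its co-members:
#' 2-fold cross-validated linear prediction; `e` is the mean absolute
#' held-out error and `e_shuffled` the median, over `n_shuffles` random
#' permutations of the predictions relative to the observations, of the
#' per-shuffle mean absolute error. The gain is `g = e_shuffled / e - 1`
#' (0 when prediction is no better than shuffle). The mean (not a bin-wise
#' median) is used because binned spike trains are sparse enough that the
#' median absolute error degenerates to the empty-bin point mass.
#'
#' @param Z a z-scored `binned_matrix`.
#' @param assembly an `assembly_model` (or any vector of >= 2 unit ids).
#' @param n_shuffles shuffle repeats (default 50).
#' @param seed RNG seed.
#' @return named numeric vector of gains, one per member (`Inf` with a
#'   warning if a member's error is exactly zero).
#' @export
peer_prediction_gain <- function(Z, assembly, n_shuffles = 50, seed = 1L) {
  members <- if (inherits(assembly, "assembly_model")) assembly$members else assembly
  members <- intersect(members, Z$units)
  if (length(members) < 2) stop("need >= 2 members present in the matrix")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  q <- ncol(Z$values)
  fold <- rep(1:2, length.out = q)
  g <- stats::setNames(numeric(length(members)), members)
  for (mi in seq_along(members)) {
    yi <- Z$values[match(members[mi], Z$units), ]
    Xi <- t(Z$values[match(setdiff(members, members[mi]), Z$units), , drop = FALSE])
    pred <- numeric(q)
    for (f in 1:2) {
      tr <- fold != f; te <- fold == f
      fit <- stats::lm.fit(cbind(1, Xi[tr, , drop = FALSE]), yi[tr])
      pred[te] <- cbind(1, Xi[te, , drop = FALSE]) %*% fit$coefficients
    }
    e <- mean(abs(pred - yi))
    esh <- stats::median(vapply(seq_len(n_shuffles), function(s)
      mean(abs(sample(pred) - yi)), numeric(1)))
    if (e == 0) {
      warning("zero prediction error for member ", members[mi])
      g[mi] <- Inf
    } else g[mi] <- esh / e - 1
  }
  g
}

#' Z-scored cross-correlograms between unit pairs
#'
#' Cross-correlogram of each pair (counts of spike-time differences in
#' `bin_ms` bins over +/- `window_ms`), z-scored against its own mean and sd
#' across lags; the mode (lag of the maximum) summarizes each pair's
#' synchrony delay. Member pairs of a genuine assembly concentrate their
#' modes at brief delays, unlike control pairs.
#'
#' @param spikes a `spike_data` object.
#' @param pairs two-column matrix of unit ids.
#' @param window_ms,bin_ms correlogram extent and bin width.
#' @param min_spikes pairs where either train has fewer spikes are skipped.
#' @return data.frame (`unit1`, `unit2`, `mode_ms`, `peak_z`, `n1`, `n2`)
#'   plus attribute `ccg` (matrix of z-scored correlograms, one row per
#'   retained pair) and `lags_ms`.
#' @export
member_synchrony_ccg <- function(spikes, pairs, window_ms = 100, bin_ms = 5,
                                 min_spikes = 100) {
  w <- window_ms / 1000; b <- bin_ms / 1000
  edges <- seq(-w, w, by = b)
  lags <- (edges[-1] + edges[-length(edges)]) / 2 * 1000
  rows <- list(); meta <- list()
  for (r in seq_len(nrow(pairs))) {
    t1 <- unit_spikes(spikes, pairs[r, 1])
    t2 <- unit_spikes(spikes, pairs[r, 2])
    if (length(t1) < min_spikes || length(t2) < min_spikes) next
    cc <- numeric(length(lags))
    for (i in seq_along(t1)) {
      lo <- findInterval(t1[i] - w, t2) + 1
      hi <- findInterval(t1[i] + w, t2)
      if (hi >= lo) {
        d <- t2[lo:hi] - t1[i]
        ix <- pmin(pmax(floor((d + w) / b) + 1, 1), length(lags))
        cc <- cc + tabulate(ix, nbins = length(lags))
      }
    }
    z <- (cc - mean(cc)) / max(stats::sd(cc), 1e-12)
    rows[[length(rows) + 1]] <- z
    meta[[length(meta) + 1]] <- data.frame(
      unit1 = pairs[r, 1], unit2 = pairs[r, 2],
      mode_ms = lags[which.max(z)], peak_z = max(z),
      n1 = length(t1), n2 = length(t2))
  }
  out <- if (length(meta)) do.call(rbind, meta) else
    data.frame(unit1 = integer(0), unit2 = integer(0), mode_ms = numeric(0),
               peak_z = numeric(0), n1 = integer(0), n2 = integer(0))
  attr(out, "ccg") <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, length(lags))
  attr(out, "lags_ms") <- lags
  out
}
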
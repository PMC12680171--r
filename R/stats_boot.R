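#' Hierarchical bootstrap for nested observations
#'
#' Resamples with replacement following the nesting order: animals first,
#' then sessions within each drawn animal, then observations within each
#' drawn session, with the number of draws at each level equal to the
#' observed count at that level. The statistic (mean or median) is computed
#' on each resampled dataset; the percentile interval of the resampled
#' statistics quantifies the estimate's reliability while respecting the
#' dependence between observations from the same session or animal.
#'
#' @param values numeric observations.
#' @param animal,session labels parallel to `values`.
#' @param statistic "mean" or "median".
#' @param repeats bootstrap repeats (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param level CI level (default 0.95).
#' @return list with `estimate` (statistic on the original data),
#'   `resampled` (length `repeats`), `ci` (percentile bounds), `repeats`.
#' @export
hierarchical_bootstrap <- function(values, animal, session,
                                   statistic = c("mean", "median"),
                                   repeats = 1000, seed = 1L, level = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == length(animal), length(values) == length(session),
            repeats >= 100)
  if (anyNA(values) || anyNA(animal) || anyNA(session))
    stop("every observation must be labelled and non-missing")
  stat_fun <- if (statistic == "mean") mean else stats::median
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  key <- paste(animal, session, sep = "\r")
  obs_by_session <- split(seq_along(values), key)
  sess_by_animal <- split(unique(key), sub("\r.*$", "", unique(key)))
  animals <- names(sess_by_animal)
  n_an <- length(animals)
  res <- numeric(repeats)
  for (b in seq_len(repeats)) {
    repeat {
      idx_all <- integer(0)
      an_draw <- animals[sample.int(n_an, n_an, replace = TRUE)]
      for (a in an_draw) {
        ss <- sess_by_animal[[a]]
        s_draw <- ss[sample.int(length(ss), length(ss), replace = TRUE)]
        for (s in s_draw) {
          obs <- obs_by_session[[s]]
          idx_all <- c(idx_all, obs[sample.int(length(obs), length(obs), replace = TRUE)])
        }
      }
      if (length(idx_all)) break
    }
    res[b] <- stat_fun(values[idx_all])
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(res, c(alpha, 1 - alpha), names = FALSE, type = 1)
  list(estimate = stat_fun(values), resampled = res, ci = ci, repeats = repeats)
}
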
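#' Pre/post change in an assembly-reader response
#'
#' The change statistic is the mean 10-30 ms reader response over post-epoch
#' activations minus the mean over pre-epoch activations. The null
#' distribution permutes the pre/post labels over the pooled activations
#' (group sizes preserved); a pair is called "increase"/"decrease" when the
#' observed delta lies outside the central 95% of the null.
#'
#' @param reader_times reader spike times (s).
#' @param pre_peaks,post_peaks activation peak times per epoch.
#' @param pre_epochs,post_epochs the two epochs (used for the >= 30-spike
#'   testability floor on each epoch's PETH).
#' @param response_window_ms response window (ms).
#' @param n_perm label permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `testable`, `delta`, `p`, `direction` ("increase",
#'   "decrease" or "none"), `response_pre`, `response_post`, `null`.
#' @export
response_change <- function(reader_times, pre_peaks, post_peaks,
                            pre_epochs = NULL, post_epochs = NULL,
                            response_window_ms = c(10, 30),
                            n_perm = 1000, seed = 1L, min_spikes = 30) {
  not_testable <- list(testable = FALSE, delta = NA_real_, p = NA_real_,
                       direction = NA_character_, response_pre = NA_real_,
                       response_post = NA_real_, null = NULL)
  if (!length(pre_peaks) || !length(post_peaks)) return(not_testable)
  # testability: enough reader spikes around the peaks of each epoch
  n_near <- function(p) sum(.event_window_counts(reader_times, p, -1, 1))
  if (n_near(pre_peaks) < min_spikes || n_near(post_peaks) < min_spikes)
    return(not_testable)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  lo <- response_window_ms[1] / 1000; hi <- response_window_ms[2] / 1000
  c_pre <- .event_window_counts(reader_times, pre_peaks, lo, hi)
  c_post <- .event_window_counts(reader_times, post_peaks, lo, hi)
  delta <- mean(c_post) - mean(c_pre)
  pooled <- c(c_pre, c_post)
  n <- length(pooled); n_post <- length(c_post)
  tot <- sum(pooled)
  null <- vapply(seq_len(n_perm), function(s) {
    ix <- sample.int(n, n_post)
    sp <- sum(pooled[ix])
    sp / n_post - (tot - sp) / (n - n_post)
  }, numeric(1))
  p <- 2 * min(mean(null >= delta), mean(null <= delta))
  qs <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
  direction <- if (delta > qs[2]) "increase" else if (delta < qs[1]) "decrease" else "none"
  list(testable = TRUE, delta = delta, p = p, direction = direction,
       response_pre = mean(c_pre), response_post = mean(c_post), null = null)
}

#' Chi-squared contrast of change rates between two conditions
#'
#' 2x2 test (changed vs unchanged, condition A vs B) without continuity
#' correction. When any expected cell count falls below 5 the exact
#' (Fisher) test is used instead and flagged.
#'
#' @param sig_a,n_a significant and total tested pairs in condition A.
#' @param sig_b,n_b same for condition B.
#' @return list with `statistic` (NA for the exact fallback), `p`,
#'   `prop_a`, `prop_b`, `method`.
#' @export
compare_change_rates <- function(sig_a, n_a, sig_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1, sig_a <= n_a, sig_b <= n_b)
  tab <- matrix(c(sig_a, n_a - sig_a, sig_b, n_b - sig_b), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    message("expected cell count < 5; exact test fallback")
    return(list(statistic = NA_real_, p = ft$p.value,
                prop_a = sig_a / n_a, prop_b = sig_b / n_b, method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       prop_a = sig_a / n_a, prop_b = sig_b / n_b, method = "chisq")
}
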
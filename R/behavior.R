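#' Score the orthogonal color-detection task
#'
#' Each color-change onset is matched greedily to the first subsequent
#' unmatched key press; a response is correct when its reaction time falls
#' in the `window` (150-1000 ms by default). Presses with no prior onset are
#' counted as false alarms.
#'
#' @param onsets color-change onset times, s (nondecreasing).
#' @param presses key-press times, s (nondecreasing).
#' @param window correct-response window, s.
#' @return list with `accuracy_pct`, `mean_rt_ms` (over correct responses;
#'   NA if none), `n_onsets`, `n_correct`, `false_alarms`.
#' @export
score_detection_task <- function(onsets, presses, window = c(0.150, 1.000)) {
  if (!length(onsets)) stopf("no color-change onsets to score")
  if (is.unsorted(onsets) || is.unsorted(presses))
    stopf("onsets and presses must be nondecreasing")
  rts <- rep(NA_real_, length(onsets))
  used <- rep(FALSE, length(presses))
  for (i in seq_along(onsets)) {
    j <- which(!used & presses >= onsets[i])
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      rts[i] <- presses[j] - onsets[i]
    }
  }
  false_alarms <- sum(!used & presses < onsets[1])
  correct <- !is.na(rts) & rts >= window[1] & rts <= window[2]
  list(accuracy_pct = 100 * mean(correct),
       mean_rt_ms = if (any(correct)) 1000 * mean(rts[correct]) else NA_real_,
       n_onsets = length(onsets), n_correct = sum(correct),
       false_alarms = false_alarms)
}
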
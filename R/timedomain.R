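#' Prepare a segment for time-domain analysis
#'
#' Zero-phase 30 Hz low-pass of the (preprocessed, re-referenced) segment,
#' then cropping to the same integer-cycle window used in the frequency
#' domain (2 to 71.17 s, 83 oddball cycles, by default).
#'
#' @param seg an `fpvs_segment` from [preprocess_recording()].
#' @param cutoff low-pass cutoff, Hz.
#' @param order Butterworth design order.
#' @param oddball_freq,start,n_cycles cropping parameters, see
#'   [crop_integer_cycles()].
#' @return An `fpvs_epoch` (channels x time) ready for
#'   [remove_base_harmonics()].
#' @export
prepare_waveforms <- function(seg, cutoff = 30, order = 4,
                              oddball_freq = 1.2, start = 2, n_cycles = 83) {
  seg <- filter_lowpass(seg, cutoff = cutoff, order = order)
  crop_integer_cycles(seg, oddball_freq = oddball_freq, start = start,
                      n_cycles = n_cycles)
}

#' Remove the base stimulation frequency and its harmonics
#'
#' Narrow zero-phase notch filters (4th-order band-stop) at the base
#' frequency and its harmonics up to `up_to` Hz (6, 12, 18, 24, 30 Hz by
#' default), leaving the oddball harmonics untouched.
#'
#' @param ep an `fpvs_epoch` (or recording-like object).
#' @param base base stimulation frequency, Hz.
#' @param up_to highest harmonic to remove, Hz.
#' @param width full notch width, Hz.
#' @param order band-stop design order.
#' @return the filtered epoch.
#' @export
remove_base_harmonics <- function(ep, base = 6, up_to = 30, width = 0.05,
                                  order = 4) {
  if (up_to >= ep$rate / 2) stopf("up_to must be below Nyquist")
  centers <- seq(base, up_to, by = base)
  out <- ep
  out$samples <- apply_gain(ep$samples, ep$rate,
                            gain_notches(centers, width, order, ep$rate))
  out
}

#' Epoch around oddball onsets and average
#'
#' Cuts one epoch per complete oddball cycle, spanning five stimulation
#' cycles (833 ms at 6 Hz): one base cycle of pre-stimulus context (-167 to
#' 0 ms) and four cycles after the oddball onset at t = 0. Epochs are
#' averaged and baseline-corrected to the mean of the pre-stimulus window
#' per channel.
#'
#' @param ep an integer-cycle cropped `fpvs_epoch` whose time origin is the
#'   crop start (`start` seconds after sequence onset).
#' @param oddball_freq,base_freq stimulation frequencies, Hz.
#' @param crop_start_s crop start relative to sequence onset, s (used to
#'   locate oddball onsets, which fall at multiples of the oddball period in
#'   sequence time).
#' @return An object of class `fpvs_epoch_average`: `waveform` (channels x
#'   time, uV), `time_ms` (-167 ... +667), `n_epochs`, `baseline_ms`.
#' @export
epoch_and_average <- function(ep, oddball_freq = 1.2, base_freq = 6,
                              crop_start_s = 2) {
  rate <- ep$rate
  cyc <- 1 / oddball_freq
  base_cyc <- 1 / base_freq
  pre_n <- round(base_cyc * rate)
  len <- round(5 * base_cyc * rate)
  n <- ncol(ep$samples)
  # oddball onsets at multiples of the oddball period in sequence time
  k0 <- ceiling((crop_start_s + base_cyc) / cyc - 1e-9)
  onsets_s <- k0 * cyc + seq(0, by = cyc,
                             length.out = floor(n / (cyc * rate)) + 2) -
    crop_start_s
  starts <- round((onsets_s - base_cyc) * rate) + 1L
  keep <- starts >= 1L & starts + len - 1L <= n
  starts <- starts[keep]
  if (!length(starts)) stopf("no complete five-cycle epoch fits the input")
  acc <- matrix(0, nrow(ep$samples), len)
  for (s in starts) acc <- acc + ep$samples[, s:(s + len - 1L), drop = FALSE]
  wav <- acc / length(starts)
  time_ms <- ((0:(len - 1)) - pre_n) / rate * 1000
  bl <- time_ms >= -base_cyc * 1000 - 1e-9 & time_ms <= 0
  wav <- wav - rowMeans(wav[, bl, drop = FALSE])
  structure(
    list(waveform = wav, time_ms = time_ms, n_epochs = length(starts),
         baseline_ms = c(-base_cyc * 1000, 0), rate = rate,
         channel_labels = ep$channel_labels,
         condition = ep$condition, participant_id = ep$participant_id),
    class = "fpvs_epoch_average"
  )
}

#' Mean waveform over a channel group
#'
#' @param avg an [epoch_and_average()] result.
#' @param channels channel labels to average.
#' @return numeric vector (time course, uV).
#' @export
roi_waveform <- function(avg, channels) {
  missing <- setdiff(channels, avg$channel_labels)
  if (length(missing))
    stopf("channel(s) missing: %s", paste(missing, collapse = ", "))
  colMeans(avg$waveform[channels, , drop = FALSE])
}

# t statistics per column for rows of x (one-sample vs 0), handling
# zero-variance columns by flagging them (t = 0, never significant).
col_tstats <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1)
  degen <- v <= 0
  tt <- ifelse(degen, 0, m / sqrt(v / n))
  list(t = tt, df = n - 1, degenerate = degen)
}

clusters_from_t <- function(tt, df, alpha) {
  p <- 2 * pt(-abs(tt), df)
  supra <- p < alpha
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep),
                           function(i) sum(tt[starts[i]:ends[i]]), 1.0))
}

# mass of the largest-|mass| cluster per row of a t-statistic matrix
max_cluster_mass_rows <- function(tmat, df, alpha) {
  crit <- stats::qt(1 - alpha / 2, df)
  supra <- abs(tmat) > crit
  out <- numeric(nrow(tmat))
  for (i in seq_len(nrow(tmat))) {
    s <- supra[i, ]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    masses <- vapply(which(r$values),
                     function(j) sum(tmat[i, starts[j]:ends[j]]), 1.0)
    out[i] <- masses[which.max(abs(masses))]
  }
  out
}

cluster_test_core <- function(D, time_ms, window, n_perm, point_alpha, seed,
                              add_one) {
  if (n_perm < 100) warnf("n_perm = %d is very small", n_perm)
  sel <- time_ms >= window[1] & time_ms <= window[2]
  D <- D[, sel, drop = FALSE]
  tm <- time_ms[sel]
  n <- nrow(D)
  obs <- col_tstats(D)
  cl <- clusters_from_t(obs$t, obs$df, point_alpha)
  # permutation null: per-participant sign flips, fully vectorized
  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  M <- signs %*% D / n
  ss <- colSums(D^2)
  V <- (matrix(ss, n_perm, ncol(D), byrow = TRUE) - n * M^2) / (n - 1)
  Tmat <- M / sqrt(pmax(V, 1e-300) / n)
  Tmat[V <= 0] <- 0
  null <- max_cluster_mass_rows(Tmat, n - 1, point_alpha)
  q <- quantile(null, c(0.025, 0.975), names = FALSE, type = 7)
  if (nrow(cl)) {
    cl$start_ms <- tm[cl$start]
    cl$end_ms <- tm[cl$end]
    cl$p <- vapply(cl$mass, function(m) {
      if (add_one) {
        pmin(1, 2 * min((1 + sum(null >= m)) / (1 + n_perm),
                        (1 + sum(null <= m)) / (1 + n_perm)))
      } else {
        pmin(1, 2 * min(mean(null >= m), mean(null <= m)))
      }
    }, 1.0)
    cl$significant <- cl$mass > q[2] | cl$mass < q[1]
  } else {
    cl <- data.frame(start = integer(0), end = integer(0), mass = numeric(0),
                     start_ms = numeric(0), end_ms = numeric(0),
                     p = numeric(0), significant = logical(0))
  }
  structure(
    list(clusters = cl, null = null, n_perm = n_perm,
         point_alpha = point_alpha, window = window, time_ms = tm,
         t = obs$t, df = obs$df, degenerate_points = sum(obs$degenerate)),
    class = "fpvs_cluster_test"
  )
}

#' @export
print.fpvs_cluster_test <- function(x, ...) {
  cat(sprintf("<fpvs_cluster_test> %d permutation(s), window %g..%g ms\n",
              x$n_perm, x$window[1], x$window[2]))
  if (nrow(x$clusters)) {
    print(x$clusters[, c("start_ms", "end_ms", "mass", "p", "significant")],
          row.names = FALSE)
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Cluster-based permutation test (paired conditions)
#'
#' Paired t-tests at each time point inside the window; clusters are maximal
#' runs of consecutive points with p < `point_alpha`, scored by the sum of
#' t-values (cluster mass). The null distribution is built by randomly
#' swapping the condition labels within participants (equivalently, flipping
#' the sign of each participant's difference waveform) and taking the
#' largest-magnitude cluster mass of each permutation. A cluster is
#' significant when its mass exceeds the 97.5th or falls below the 2.5th
#' percentile of the null (two-tailed, familywise-corrected).
#'
#' @param x,y participants x time matrices of (ROI-mean) waveforms, uV; rows
#'   are matched participants.
#' @param time_ms time axis, ms.
#' @param window analysis window in ms.
#' @param n_perm number of permutations.
#' @param point_alpha per-time-point threshold.
#' @param seed permutation RNG seed.
#' @param add_one use the add-one Monte-Carlo p-value formula instead of the
#'   plain percentile rule.
#' @return An `fpvs_cluster_test`: cluster table (start/end ms, mass, p,
#'   significance), the permutation null, and the observed t time course.
#' @export
cluster_test_paired <- function(x, y, time_ms, window = c(0, 667),
                                n_perm = 10000, point_alpha = 0.05,
                                seed = 1L, add_one = FALSE) {
  if (!all(dim(x) == dim(y)))
    stopf("paired test needs matching participants x time matrices")
  if (nrow(x) < 3) stopf("need at least 3 participants")
  cluster_test_core(x - y, time_ms, window, n_perm, point_alpha, seed, add_one)
}

#' Cluster-based permutation test against zero
#'
#' One-sample variant of [cluster_test_paired()]: t-tests of the waveforms
#' against zero, with a sign-flip permutation null.
#'
#' @inheritParams cluster_test_paired
#' @param x participants x time matrix of (ROI-mean) waveforms, uV.
#' @return An `fpvs_cluster_test`.
#' @export
cluster_test_vs_zero <- function(x, time_ms, window = c(0, 667),
                                 n_perm = 10000, point_alpha = 0.05,
                                 seed = 1L, add_one = FALSE) {
  if (nrow(x) < 3) stopf("need at least 3 participants")
  cluster_test_core(x, time_ms, window, n_perm, point_alpha, seed, add_one)
}
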
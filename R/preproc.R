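#' Zero-phase filtering machinery
#'
#' All filters in the package are applied with exactly zero phase by
#' multiplying each channel's discrete Fourier transform by the squared
#' magnitude response of the stated IIR design (the magnitude response of one
#' forward plus one backward pass of that filter) and inverting the
#' transform. FIR responses (resampling anti-alias) are applied as their
#' plain magnitude, which is already zero-phase for a symmetric kernel.
#' Circular edge effects are confined to the fade windows that the analysis
#' discards.
#'
#' @name zero-phase-filters
#' @keywords internal
NULL

# Butterworth power responses |H(f)|^2, evaluated analytically on the
# prewarped analog prototype (identical to the magnitude of the
# bilinear-transform digital design, but numerically robust even for
# extremely narrow bands, where polynomial filter coefficients are
# ill-conditioned). `rate` is the sample rate; edges in Hz.
prewarp <- function(f, rate) tan(pi * f / rate)

butter_pow_low <- function(f, cutoff, order, rate) {
  w <- prewarp(f, rate) / prewarp(cutoff, rate)
  1 / (1 + w^(2 * order))
}

butter_pow_band <- function(f, low, high, order, rate, stop = FALSE) {
  w <- prewarp(f, rate)
  w1 <- prewarp(low, rate); w2 <- prewarp(high, rate)
  b <- w2 - w1; w0sq <- w1 * w2
  x <- ifelse(w == 0, Inf, (w0sq - w^2) / (b * w))   # Inf at DC -> stopband
  x[!is.finite(w)] <- Inf                            # Nyquist guard
  g <- 1 / (1 + x^(2 * order))
  if (stop) 1 - g else g
}

# Apply a two-sided-symmetric gain (function of |f|) to all channels.
apply_gain <- function(samples, rate, gain_fun) {
  n <- ncol(samples)
  half <- floor(n / 2)
  f_half <- (0:half) * rate / n
  g_half <- gain_fun(f_half)
  g <- numeric(n)
  g[1:(half + 1)] <- g_half
  if (n > 1) g[n:(half + 2)] <- g_half[2:(n - half)]
  x <- t(samples)
  out <- Re(fft_cols(fft_cols(x + 0i) * g, inverse = TRUE)) / n
  out <- t(out)
  dimnames(out) <- dimnames(samples)
  out
}

gain_bandpass <- function(low, high, order, rate) {
  function(f) butter_pow_band(f, low, high, order, rate)
}

gain_lowpass <- function(cutoff, order, rate) {
  function(f) butter_pow_low(f, cutoff, order, rate)
}

gain_notches <- function(centers, width, order, rate) {
  function(f) {
    g <- rep(1, length(f))
    for (fc in centers)
      g <- g * butter_pow_band(f, fc - width / 2, fc + width / 2, order,
                               rate, stop = TRUE)
    g
  }
}

compose_gains <- function(...) {
  funs <- list(...)
  function(f) Reduce(`*`, lapply(funs, function(g) g(f)))
}

filtered_recording <- function(rec, gain_fun) {
  out <- rec
  out$samples <- apply_gain(rec$samples, rec$rate, gain_fun)
  if (any(!is.finite(out$samples))) stopf("filtering produced non-finite samples")
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass with the magnitude response of one forward and one backward pass
#' of a Butterworth filter of the given order (the standard "zero-phase
#' Butterworth" convention in electrophysiology); removes DC.
#'
#' @param rec an [recording()] (or segment).
#' @param low,high band edges in Hz.
#' @param order filter order of the underlying one-pass design.
#' @return the filtered recording.
#' @export
filter_bandpass <- function(rec, low = 0.05, high = 100, order = 4) {
  if (high >= rec$rate / 2) stopf("high cutoff (%g) must be below Nyquist (%g)",
                                  high, rec$rate / 2)
  if (low >= high) stopf("low cutoff must be below high cutoff")
  filtered_recording(rec, gain_bandpass(low, high, order, rec$rate))
}

#' Zero-phase line-noise notch filters
#'
#' Removes the line frequency and its next `n_harmonics - 1` harmonics
#' (50, 100, 150 Hz by default) with zero-phase 2nd-order Butterworth
#' band-stop filters of total stop width `width` Hz.
#'
#' @param rec an [recording()].
#' @param line line frequency, Hz.
#' @param n_harmonics how many multiples of `line` to notch (including
#'   `line` itself).
#' @param width full stop-band width in Hz.
#' @param order order of each underlying band-stop design.
#' @return the filtered recording.
#' @export
filter_notch_lines <- function(rec, line = 50, n_harmonics = 3, width = 0.5,
                               order = 2) {
  centers <- line * seq_len(n_harmonics)
  if (max(centers) >= rec$rate / 2)
    stopf("highest notch (%g Hz) must be below Nyquist (%g Hz)",
          max(centers), rec$rate / 2)
  filtered_recording(rec, gain_notches(centers, width, order, rec$rate))
}

#' Zero-phase Butterworth low-pass filter
#'
#' @param rec an [recording()].
#' @param cutoff cutoff frequency, Hz.
#' @param order order of the underlying one-pass design.
#' @return the filtered recording.
#' @export
filter_lowpass <- function(rec, cutoff = 30, order = 4) {
  if (cutoff >= rec$rate / 2) stopf("cutoff must be below Nyquist")
  filtered_recording(rec, gain_lowpass(cutoff, order, rec$rate))
}

kaiser_fir_gain <- function(q, rate, taps = 127, beta = 7) {
  h <- signal::fir1(taps - 1, 0.9 / q, window = signal::kaiser(taps, beta))
  m <- (taps - 1) / 2
  hs <- h[(m + 1):taps]                          # symmetric half
  function(f) {
    w <- 2 * pi * f / rate
    g <- hs[1]
    for (k in seq_len(m)) g <- g + 2 * hs[k + 1] * cos(w * k)
    abs(g)
  }
}

#' Anti-aliased integer-factor resampling
#'
#' Downsamples by an integer factor after a zero-phase Kaiser-windowed FIR
#' anti-alias filter. Event times are in seconds and are preserved.
#'
#' @param rec an [recording()].
#' @param target target rate, Hz; `rec$rate / target` must be a positive
#'   integer (1 returns the input unchanged).
#' @return the resampled recording.
#' @export
resample_to <- function(rec, target = 256) {
  if (target > rec$rate) stopf("upsampling (%g -> %g Hz) is not supported",
                               rec$rate, target)
  q <- rec$rate / target
  if (abs(q - round(q)) > 1e-9)
    stopf("rate ratio %g/%g is not an integer factor", rec$rate, target)
  q <- round(q)
  if (q == 1) return(rec)
  out <- filtered_recording(rec, kaiser_fir_gain(q, rec$rate))
  out$samples <- out$samples[, seq(1, ncol(out$samples), by = q), drop = FALSE]
  out$rate <- target
  if (!is.null(out$onset_index)) out$onset_index <- (out$onset_index - 1) %/% q + 1
  out
}

#' Segment a continuous recording around sequence-onset events
#'
#' Cuts one segment per event, spanning `-pre` to `+post` seconds around the
#' event. Events too close to the record edges are skipped with a warning.
#'
#' @param rec an [recording()] with at least one event.
#' @param pre,post segment extent in seconds before/after the event.
#' @return list of `fpvs_segment` objects (recordings carrying an
#'   `onset_index` marking t = 0).
#' @export
segment_sequences <- function(rec, pre = 2, post = 76) {
  if (!nrow(rec$events)) stopf("recording has no events to segment around")
  n <- ncol(rec$samples)
  len <- round((pre + post) * rec$rate)
  segs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    ev <- rec$events$time[i]
    start <- round((ev - pre) * rec$rate) + 1L
    if (start < 1L || start + len - 1L > n) {
      skipped <- skipped + 1L
      next
    }
    seg <- rec
    seg$samples <- rec$samples[, start:(start + len - 1L), drop = FALSE]
    seg$events <- data.frame(time = pre, code = rec$events$code[i])
    seg$onset_index <- round(pre * rec$rate) + 1L
    class(seg) <- c("fpvs_segment", class(rec))
    segs[[length(segs) + 1L]] <- seg
  }
  if (skipped > 0L)
    warnf("skipped %d event(s) without full [-%g, +%g] s support", skipped,
          pre, post)
  segs
}

#' Average re-referencing
#'
#' Re-expresses every channel relative to the mean of all channels at each
#' sample, so the channel mean is zero everywhere.
#'
#' @param rec an [recording()] with at least two channels.
#' @return the re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$samples) < 2) stopf("average reference requires >= 2 channels")
  m <- colMeans(rec$samples)
  rec$samples <- rec$samples - matrix(m, nrow(rec$samples),
                                      ncol(rec$samples), byrow = TRUE)
  rec
}

#' Standard preprocessing chain
#'
#' Band-pass filter, line-noise notches, anti-aliased downsampling, sequence
#' segmentation and per-segment average re-referencing, in that order. The
#' band-pass and notch responses are composed and applied in a single
#' zero-phase pass per recording.
#'
#' @param rec an [recording()].
#' @param low,high,order band-pass parameters (Hz / Hz / design order).
#' @param line,n_line_harmonics,notch_width line-notch parameters; set
#'   `notch = FALSE` to skip the notches.
#' @param notch logical, apply line notches.
#' @param resample target rate in Hz (NULL to keep the native rate).
#' @param pre,post segmentation window, s.
#' @return list of preprocessed `fpvs_segment` objects.
#' @export
preprocess_recording <- function(rec, low = 0.05, high = 100, order = 4,
                                 line = 50, n_line_harmonics = 3,
                                 notch_width = 0.5, notch = TRUE,
                                 resample = 256, pre = 2, post = 76) {
  if (high >= rec$rate / 2) stopf("band-pass high edge must be below Nyquist")
  g <- gain_bandpass(low, high, order, rec$rate)
  if (notch) {
    centers <- line * seq_len(n_line_harmonics)
    if (max(centers) >= rec$rate / 2)
      stopf("line notches exceed Nyquist; lower n_line_harmonics or disable")
    g <- compose_gains(g, gain_notches(centers, notch_width, 2, rec$rate))
  }
  out <- filtered_recording(rec, g)
  if (!is.null(resample)) out <- resample_to(out, resample)
  segs <- segment_sequences(out, pre = pre, post = post)
  lapply(segs, rereference_average)
}
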
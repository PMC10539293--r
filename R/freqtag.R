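#' Region-of-interest channel layout
#'
#' The standard posterior channel groups used to summarize the oddball and
#' base responses: bilateral occipito-temporal (OT) left/right groups of 5
#' channels each, their 10-channel union, and a 12-channel middle-occipital
#' (MO) group.
#'
#' @return named list of character vectors: `OT_left`, `OT_right`, `OT`,
#'   `MO`.
#' @export
roi_layout <- function() {
  ot_l <- c("P7", "P9", "PO7", "PO9", "PO11")
  ot_r <- c("P8", "P10", "PO8", "PO10", "PO12")
  list(OT_left = ot_l, OT_right = ot_r, OT = c(ot_l, ot_r),
       MO = c("POOz", "Oz", "OIz", "Iz", "POO5", "POO6", "O1", "O2",
              "POI1", "POI2", "I1", "I2"))
}

#' Neighbor-bin specification for noise estimation
#'
#' The noise level at a frequency bin is estimated from `n_per_side` bins on
#' each side, excluding the `skip_adjacent` immediately adjacent bins (which
#' may carry spectral leakage). Defaults give the standard 48 noise bins at
#' offsets +/-2 ... +/-25.
#'
#' @param n_per_side noise bins per side.
#' @param skip_adjacent adjacent bins to exclude per side.
#' @return An object of class `fpvs_neighbor_spec` with the offset vector.
#' @export
neighbor_spec <- function(n_per_side = 24, skip_adjacent = 1) {
  off <- (skip_adjacent + 1):(skip_adjacent + n_per_side)
  structure(list(n_per_side = n_per_side, skip_adjacent = skip_adjacent,
                 offsets = c(-rev(off), off)),
            class = "fpvs_neighbor_spec")
}

#' Crop a segment to an integer number of oddball cycles
#'
#' Removes the fade-in by starting `start` seconds after the sequence onset
#' and keeps exactly `n_cycles` oddball cycles (rounded to the nearest
#' sample). With the standard timing (74 s sequences, 2 s fades, 1.2 Hz) the
#' default reproduces the 83-cycle, 69.17 s epoch used for replication; pass
#' `n_cycles = "max"` for the largest count that fits the usable span.
#'
#' @param seg an `fpvs_segment` from [segment_sequences()] (or any recording
#'   with an `onset_index`).
#' @param oddball_freq oddball frequency, Hz.
#' @param start crop start relative to sequence onset, s (end of fade-in).
#' @param n_cycles integer cycle count, or "max".
#' @param usable_end end of the steady-state span relative to onset, s (start
#'   of fade-out); only used to resolve `n_cycles = "max"` and to validate.
#' @return An object of class `fpvs_epoch`: channels x time samples plus
#'   `rate`, `n_cycles`, `duration` and `oddball_freq`.
#' @export
crop_integer_cycles <- function(seg, oddball_freq = 1.2, start = 2,
                                n_cycles = 83, usable_end = NULL) {
  onset <- seg$onset_index %||% 1L
  rate <- seg$rate
  avail_s <- (ncol(seg$samples) - onset + 1) / rate
  if (identical(n_cycles, "max")) {
    end_s <- min(avail_s, usable_end %||% avail_s)
    n_cycles <- floor((end_s - start) * oddball_freq)
  }
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1) stopf("no complete oddball cycle fits the requested span")
  len <- round(n_cycles / oddball_freq * rate)
  i0 <- onset + round(start * rate)
  if (i0 + len - 1 > ncol(seg$samples))
    stopf("%d cycles (%.2f s) exceed the available span (%.2f s after start)",
          n_cycles, len / rate, avail_s - start)
  if (!is.null(usable_end) && start + n_cycles / oddball_freq > usable_end)
    stopf("%d cycles extend past the usable steady-state span", n_cycles)
  structure(
    list(samples = seg$samples[, i0:(i0 + len - 1), drop = FALSE],
         rate = rate, channel_labels = seg$channel_labels,
         n_cycles = n_cycles, duration = len / rate,
         oddball_freq = oddball_freq,
         condition = seg$condition, participant_id = seg$participant_id),
    class = "fpvs_epoch"
  )
}

#' Single-sided amplitude spectrum
#'
#' FFT amplitude spectrum of a cropped epoch, normalized so a bin-centered
#' sinusoid of peak amplitude A yields A at its bin (2/N scaling; DC
#' unscaled). The frequency resolution is 1/duration.
#'
#' @param ep an [crop_integer_cycles()] epoch (or any channels x time object
#'   with `samples` and `rate`).
#' @return An object of class `fpvs_spectrum` (`kind = "raw"`): `amplitude`
#'   (channels x bins, uV), `freqs` (Hz, starting at 0), `resolution`
#'   (Hz/bin).
#' @export
amplitude_spectrum <- function(ep) {
  n <- ncol(ep$samples)
  if (n < 2) stopf("empty epoch")
  if (any(!is.finite(ep$samples))) stopf("epoch contains non-finite samples")
  sp <- fft_cols(t(ep$samples) + 0i)
  half <- floor(n / 2)
  amp <- t(Mod(sp[1:(half + 1), , drop = FALSE])) * (2 / n)
  amp[, 1] <- amp[, 1] / 2
  rownames(amp) <- ep$channel_labels
  structure(
    list(amplitude = amp, freqs = (0:half) * ep$rate / n,
         resolution = ep$rate / n, kind = "raw",
         channel_labels = ep$channel_labels,
         condition = ep$condition, participant_id = ep$participant_id),
    class = "fpvs_spectrum"
  )
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum kind=%s> %d channels x %d bins, %.5f Hz/bin\n",
              x$kind, nrow(x$amplitude), ncol(x$amplitude), x$resolution))
  invisible(x)
}

# Nearest bin index (1-based) for a frequency; errors if not bin-centered.
bin_at <- function(spec, freq, tol = spec$resolution / 2) {
  k <- as.integer(round(freq / spec$resolution)) + 1L
  if (k < 1L || k > length(spec$freqs))
    stopf("frequency %.4g Hz outside spectrum range", freq)
  if (abs(spec$freqs[k] - freq) > tol)
    stopf("frequency %.4g Hz is not bin-centered (nearest bin %.4g Hz)",
          freq, spec$freqs[k])
  k
}

# Neighbor mean/SD matrices for every bin with full support; NA elsewhere.
neighbor_stats <- function(spec, nb) {
  amp <- spec$amplitude
  nbin <- ncol(amp)
  offs <- nb$offsets
  lo <- 1 - min(offs); hi <- nbin - max(offs)
  s <- matrix(0, nrow(amp), nbin)
  s2 <- matrix(0, nrow(amp), nbin)
  valid <- seq(lo, hi)
  for (o in offs) {
    s[, valid] <- s[, valid] + amp[, valid + o, drop = FALSE]
    s2[, valid] <- s2[, valid] + amp[, valid + o, drop = FALSE]^2
  }
  k <- length(offs)
  mu <- s / k
  sdv <- sqrt(pmax((s2 - k * mu^2) / (k - 1), 0))
  mu[, -valid] <- NA; sdv[, -valid] <- NA
  list(mean = mu, sd = sdv, valid = valid)
}

#' Neighbor-bin SNR spectrum
#'
#' Divides each bin's amplitude by the mean amplitude of its noise bins
#' (see [neighbor_spec()]). Under noise alone the SNR is ~1. Edge bins
#' without full neighbor support are NA.
#'
#' @param spec a raw [amplitude_spectrum()].
#' @param nb a [neighbor_spec()].
#' @return An `fpvs_spectrum` with `kind = "snr"`.
#' @export
snr_spectrum <- function(spec, nb = neighbor_spec()) {
  stopifnot(spec$kind == "raw")
  ns <- neighbor_stats(spec, nb)
  zero <- !is.na(ns$mean) & ns$mean == 0
  if (any(zero)) warnf("%d bin(s) with zero neighbor mean: SNR set to +Inf",
                       sum(zero))
  out <- spec
  out$amplitude <- spec$amplitude / ns$mean
  out$amplitude[zero] <- Inf
  out$kind <- "snr"
  out
}

#' Baseline-subtracted amplitude spectrum
#'
#' Subtracts the neighbor-bin mean amplitude from each bin, yielding a
#' signal-amplitude estimate in microvolts (possibly negative under noise).
#'
#' @inheritParams snr_spectrum
#' @return An `fpvs_spectrum` with `kind = "sbl"`.
#' @export
baseline_subtract <- function(spec, nb = neighbor_spec()) {
  stopifnot(spec$kind == "raw")
  ns <- neighbor_stats(spec, nb)
  out <- spec
  out$amplitude <- spec$amplitude - ns$mean
  out$kind <- "sbl"
  out
}

#' Noise-bin z-score at one frequency
#'
#' z = (amplitude - neighbor mean) / neighbor SD (SD with n-1), per channel.
#'
#' @param spec a raw [amplitude_spectrum()].
#' @param freq bin-centered frequency, Hz.
#' @param nb a [neighbor_spec()].
#' @return named numeric vector, one z per channel.
#' @export
zscore_bin <- function(spec, freq, nb = neighbor_spec()) {
  stopifnot(spec$kind == "raw")
  k <- bin_at(spec, freq)
  offs <- nb$offsets
  if (k + min(offs) < 1 || k + max(offs) > ncol(spec$amplitude))
    stopf("bin at %.4g Hz lacks full neighbor support", freq)
  nbr <- spec$amplitude[, k + offs, drop = FALSE]
  mu <- rowMeans(nbr)
  sdv <- apply(nbr, 1, sd)
  if (any(sdv == 0)) warnf("zero neighbor SD: z set to +Inf")
  z <- (spec$amplitude[, k] - mu) / sdv
  z[sdv == 0] <- Inf
  setNames(z, spec$channel_labels)
}

#' Harmonic set
#'
#' @param fundamental fundamental frequency, Hz.
#' @param harmonics harmonic frequencies retained, Hz.
#' @param excluded candidate harmonics excluded as multiples of another
#'   frequency, Hz.
#' @param z_threshold selection threshold used.
#' @return An object of class `fpvs_harmonic_set`.
#' @export
harmonic_set <- function(fundamental, harmonics, excluded = numeric(0),
                         z_threshold = 2.3) {
  k <- harmonics / fundamental
  if (any(abs(k - round(k)) > 1e-6))
    stopf("harmonics must be integer multiples of the fundamental")
  structure(list(fundamental = fundamental, harmonics = harmonics,
                 excluded = excluded, z_threshold = z_threshold),
            class = "fpvs_harmonic_set")
}

#' @export
print.fpvs_harmonic_set <- function(x, ...) {
  cat(sprintf("<fpvs_harmonic_set> %g Hz: {%s} Hz%s\n", x$fundamental,
              paste(format(x$harmonics), collapse = ", "),
              if (length(x$excluded))
                paste0(" (excluded: ", paste(format(x$excluded), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Select consecutive significant harmonics
#'
#' Walks k = 1, 2, ... over k x fundamental up to `f_max`, skipping
#' candidates that are integer multiples of `exclude_multiples_of` (within
#' half a bin), and keeps consecutive harmonics whose grand-average noise-bin
#' z exceeds `z_threshold`; the walk stops at the first non-significant
#' candidate. Applied to the grand-averaged spectrum (across participants,
#' channels and conditions); multi-channel input is averaged internally.
#'
#' @param grand_spec a raw [amplitude_spectrum()] (grand average).
#' @param fundamental fundamental frequency, Hz.
#' @param exclude_multiples_of frequency whose multiples are skipped (e.g.
#'   the base rate when selecting oddball harmonics), or NULL.
#' @param z_threshold one-tailed selection threshold (2.3 ~ p < 0.01).
#' @param f_max highest candidate frequency, Hz.
#' @param nb a [neighbor_spec()].
#' @return An [harmonic_set()].
#' @export
select_harmonics <- function(grand_spec, fundamental,
                             exclude_multiples_of = NULL, z_threshold = 2.3,
                             f_max = 100, nb = neighbor_spec()) {
  stopifnot(grand_spec$kind == "raw")
  spec <- grand_spec
  if (nrow(spec$amplitude) > 1) {
    spec$amplitude <- matrix(colMeans(spec$amplitude), 1)
    spec$channel_labels <- "grand"
  }
  sel <- numeric(0)
  excl <- numeric(0)
  half_bin <- spec$resolution / 2
  k <- 1
  repeat {
    f <- k * fundamental
    if (f > f_max ||
        f > spec$freqs[length(spec$freqs)] - max(nb$offsets) * spec$resolution)
      break
    skip <- FALSE
    if (!is.null(exclude_multiples_of)) {
      m <- f / exclude_multiples_of
      if (abs(m - round(m)) * exclude_multiples_of < half_bin) {
        excl <- c(excl, f)
        skip <- TRUE
      }
    }
    if (!skip) {
      z <- zscore_bin(spec, f, nb)
      if (z > z_threshold) sel <- c(sel, f) else break
    }
    k <- k + 1
  }
  harmonic_set(fundamental, sel, excluded = excl, z_threshold = z_threshold)
}

#' Summed-harmonic response amplitude
#'
#' Sums baseline-subtracted amplitudes over the harmonic set, per channel:
#' the summed-harmonic response in microvolts.
#'
#' @param spec_sbl a [baseline_subtract()] spectrum.
#' @param hs an [harmonic_set()].
#' @return named numeric vector, one summed amplitude per channel.
#' @export
summed_response <- function(spec_sbl, hs) {
  stopifnot(spec_sbl$kind %in% c("sbl", "snr", "raw"))
  ks <- vapply(hs$harmonics, function(f) bin_at(spec_sbl, f), 1L)
  v <- rowSums(spec_sbl$amplitude[, ks, drop = FALSE])
  if (any(is.na(v))) stopf("harmonic bin(s) lack neighbor support in this spectrum")
  setNames(v, spec_sbl$channel_labels)
}

#' Summed-harmonic z-score over a region of interest
#'
#' Averages raw amplitude spectra over the ROI channels, sums the amplitude
#' over the harmonic bins, and builds the null from the 48 matching
#' neighbor-offset sums (for each offset, the sum across harmonics of the
#' amplitude at that offset from each harmonic bin). z = (signal -
#' mean(null)) / sd(null); significant (one-tailed) when z > `threshold`.
#'
#' @param spec_raw a raw [amplitude_spectrum()].
#' @param hs an [harmonic_set()].
#' @param nb a [neighbor_spec()].
#' @param channels ROI channel names (default: all channels in the
#'   spectrum).
#' @param threshold one-tailed significance threshold (1.64 ~ p < 0.05).
#' @return list with `z`, `signal` (summed amplitude, uV), `null_mean`,
#'   `null_sd`, `significant`, `n_null`.
#' @export
summed_zscore <- function(spec_raw, hs, nb = neighbor_spec(),
                          channels = NULL, threshold = 1.64) {
  stopifnot(spec_raw$kind == "raw")
  channels <- channels %||% spec_raw$channel_labels
  missing <- setdiff(channels, spec_raw$channel_labels)
  if (length(missing))
    stopf("ROI channel(s) missing from spectrum: %s",
          paste(missing, collapse = ", "))
  amp <- colMeans(spec_raw$amplitude[match(channels, spec_raw$channel_labels),
                                     , drop = FALSE])
  ks <- vapply(hs$harmonics, function(f) bin_at(spec_raw, f), 1L)
  offs <- nb$offsets
  if (min(ks) + min(offs) < 1 || max(ks) + max(offs) > length(amp))
    stopf("harmonic bins lack full neighbor support")
  signal <- sum(amp[ks])
  null_sums <- vapply(offs, function(o) sum(amp[ks + o]), 1.0)
  mu <- mean(null_sums); sdv <- sd(null_sums)
  z <- if (sdv == 0) {
    if (signal == mu) 0 else {
      warnf("zero null SD in summed z-score"); Inf * sign(signal - mu)
    }
  } else (signal - mu) / sdv
  list(z = z, signal = signal, null_mean = mu, null_sd = sdv,
       significant = is.finite(z) && z > threshold, n_null = length(offs))
}

#' Aggregate per-channel values over regions of interest
#'
#' Unweighted mean of member-channel values per ROI, plus the all-channel
#' mean.
#'
#' @param values named numeric vector (names = channel labels).
#' @param layout list of ROI channel groups (default [roi_layout()]).
#' @return named numeric vector: one mean per ROI plus `all_channels`.
#' @export
roi_aggregate <- function(values, layout = roi_layout()) {
  out <- vapply(layout, function(chs) {
    missing <- setdiff(chs, names(values))
    if (length(missing))
      stopf("ROI channel(s) missing: %s", paste(missing, collapse = ", "))
    mean(values[chs])
  }, 1.0)
  c(out, all_channels = mean(values))
}
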
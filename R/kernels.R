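#' Band-limited periodic response kernels
#'
#' The synthetic generator builds its periodic responses as trains of a fixed
#' kernel repeated at the stimulation frequency. Each kernel is the projection
#' of a documented target waveform onto a fixed set of harmonics of its
#' fundamental, so the generated train carries energy at exactly those
#' harmonics and nowhere else. Amplitudes are normalized so that the summed
#' single-sided amplitude over the kernel's harmonics equals 1: a train scaled
#' by `A` microvolts has a true summed-harmonic amplitude of exactly `A`,
#' which gives clean inject-and-recover oracles for the frequency-domain
#' quantification.
#'
#' The oddball kernel targets a biphasic identity-change response: a negative
#' lobe peaking at `neg_peak_s` and a positive lobe peaking at `pos_peak_s`
#' after oddball onset (242 and 362 ms by default), carried by the first
#' harmonics of the oddball frequency excluding any multiple of the base
#' frequency (by default harmonics 1, 2, 3, 4 and 6 of 1.2 Hz, i.e. 1.2, 2.4,
#' 3.6, 4.8 and 7.2 Hz). The base kernel targets a brief positive deflection
#' at `peak_s` carried by the first `n_harmonics` harmonics of the base
#' frequency (6 to 60 Hz by default).
#'
#' @param fundamental fundamental frequency in Hz.
#' @param harmonics integer harmonic numbers to retain.
#' @param neg_peak_s,pos_peak_s lobe peak latencies in seconds (oddball).
#' @param neg_sd_s,pos_sd_s lobe widths (Gaussian SD) in seconds (oddball).
#' @param peak_s,sd_s pulse latency and width in seconds (base).
#' @param n_harmonics number of base harmonics to retain.
#' @param amp_profile optional relative amplitude per retained harmonic,
#'   overriding the projection amplitudes (phases are kept). The oddball
#'   default emulates the decaying harmonic profile of measured oddball
#'   responses, which carry their largest amplitude at the fundamental.
#' @return An object of class `fpvs_kernel`: a list with `freqs` (Hz), `amp`
#'   (single-sided amplitudes summing to 1), `phase` (radians), `fundamental`
#'   and `support_end_s` (latest latency carrying appreciable target energy).
#' @examples
#' k <- oddball_kernel()
#' sum(k$amp)  # 1 by construction
#' @export
oddball_kernel <- function(fundamental = 1.2, harmonics = c(1, 2, 3, 4, 6),
                           neg_peak_s = 0.242, pos_peak_s = 0.362,
                           neg_sd_s = 0.030, pos_sd_s = 0.040,
                           amp_profile = c(1, 0.62, 0.45, 0.35, 0.22)) {
  target <- function(t) {
    -exp(-(t - neg_peak_s)^2 / (2 * neg_sd_s^2)) +
      0.8 * exp(-(t - pos_peak_s)^2 / (2 * pos_sd_s^2))
  }
  support <- max(neg_peak_s + 3 * neg_sd_s, pos_peak_s + 3 * pos_sd_s)
  band_limited_kernel(target, fundamental, harmonics, support,
                      amp_profile = amp_profile)
}

#' @rdname oddball_kernel
#' @export
base_kernel <- function(fundamental = 6, n_harmonics = 10,
                        peak_s = 0.080, sd_s = 0.004) {
  target <- function(t) exp(-(t - peak_s)^2 / (2 * sd_s^2))
  band_limited_kernel(target, fundamental, seq_len(n_harmonics),
                      peak_s + 3 * sd_s)
}

# Project a target shape (one period) onto selected harmonics.
band_limited_kernel <- function(target, fundamental, harmonics, support_end,
                                amp_profile = NULL) {
  period <- 1 / fundamental
  n <- 4800L
  tt <- (0:(n - 1)) * period / n
  g <- target(tt)
  cf <- fft(g) / n
  amp <- 2 * Mod(cf[harmonics + 1])
  phase <- Arg(cf[harmonics + 1])
  if (any(amp < 1e-8)) {
    stopf("kernel target has (near-)zero energy at harmonic(s) %s of %g Hz",
          paste(harmonics[amp < 1e-8], collapse = ", "), fundamental)
  }
  if (!is.null(amp_profile)) {
    if (length(amp_profile) != length(harmonics))
      stopf("amp_profile must have one value per harmonic")
    amp <- amp_profile
  }
  amp <- amp / sum(amp)
  structure(
    list(freqs = harmonics * fundamental, amp = amp, phase = phase,
         fundamental = fundamental, support_end_s = support_end),
    class = "fpvs_kernel"
  )
}

#' Evaluate a kernel train at given times
#'
#' Evaluates the periodic train implied by a kernel (the kernel repeated at
#' its fundamental frequency) at arbitrary time points, exactly:
#' `sum_h amp_h * cos(2 pi f_h t + phase_h)`.
#'
#' @param kernel an [oddball_kernel()] / [base_kernel()] object.
#' @param t numeric vector of times in seconds.
#' @return numeric vector of the train evaluated at `t`.
#' @export
eval_kernel <- function(kernel, t) {
  out <- numeric(length(t))
  for (h in seq_along(kernel$freqs)) {
    out <- out + kernel$amp[h] *
      cos(2 * pi * kernel$freqs[h] * t + kernel$phase[h])
  }
  out
}

#' @export
print.fpvs_kernel <- function(x, ...) {
  cat(sprintf("<fpvs_kernel> fundamental %.3g Hz, %d harmonics (%s Hz)\n",
              x$fundamental, length(x$freqs),
              paste(format(x$freqs), collapse = ", ")))
  invisible(x)
}
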
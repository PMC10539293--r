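# Shared fixtures, all built in code.

# Small fast generator configs ------------------------------------------------

# Short sequences at the native rate: 29 s stimulation (2 s fades), enough
# for a 30-cycle crop starting 2 s after onset.
short_cfg <- function(..., rate = 512, sequence_duration = 29, seed = 1L) {
  generator_config(rate = rate, sequence_duration = sequence_duration,
                   seed = seed, ...)
}

# Noise-only config at a low rate for calibration harnesses: no signal is
# generated, so the Nyquist constraint only applies to the noise band.
# Calibration of the noise-bin z runs on white noise (exponent 0), the
# exchangeable-neighbor null the statistic assumes; on 1/f spectra the
# local trend makes it conservative by construction.
noise_cfg <- function(rate = 64, seed = 1L, noise_scale = 5,
                      noise_exponent = 0) {
  generator_config(rate = rate, sequence_duration = 29,
                   base_amp = 0, oddball_amp_familiar = 0,
                   noise_scale = noise_scale, participant_gain_sd = 0,
                   noise_exponent = noise_exponent, seed = seed)
}

# Treat a whole recording as one segment with the onset at its event.
as_segment <- function(rec) {
  segment_sequences(rec, pre = 0, post = rec_duration_s(rec) -
                      rec$events$time[1])[[1]]
}

rec_duration_s <- function(rec) ncol(rec$samples) / rec$rate

# Build a recording holding given per-channel signals (time x channels ok).
signal_recording <- function(x, rate, labels = NULL, event_s = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  labels <- labels %||% paste0("ch", seq_len(nrow(x)))
  recording(x, rate, labels,
            events = data.frame(time = event_s, code = 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built amplitude spectrum object (channels x bins).
synth_spectrum <- function(amp, resolution, labels = NULL) {
  amp <- if (is.vector(amp)) matrix(amp, nrow = 1) else amp
  labels <- labels %||% paste0("ch", seq_len(nrow(amp)))
  structure(list(amplitude = amp, freqs = (0:(ncol(amp) - 1)) * resolution,
                 resolution = resolution, kind = "raw",
                 channel_labels = labels),
            class = "fpvs_spectrum")
}

# Amplitude at a frequency via FFT of a single channel (test-side oracle).
fft_amp_at <- function(x, rate, freq) {
  n <- length(x)
  a <- 2 * Mod(stats::fft(x)) / n
  a[round(freq * n / rate) + 1]
}

# Noise-only cropped spectra averaged over n_avg sequences, all channels
# (channels x bins). Channels carry independent noise, so each row is an
# independent replicate of a sequence-averaged single-channel spectrum;
# calibration harnesses consume rows (or row groups) as simulations.
noise_batch_spectra <- function(cfg, n_avg, seed, n_cycles = 30) {
  acc <- NULL
  for (s in seq_len(n_avg)) {
    rec <- generate_sequence(cfg, condition = "familiar",
                             seed = fpvstag:::derive_seed(seed, s))
    ep <- crop_integer_cycles(as_segment(rec), start = 2,
                              n_cycles = n_cycles)
    sp <- amplitude_spectrum(ep)
    acc <- if (is.null(acc)) sp$amplitude else acc + sp$amplitude
  }
  list(amplitude = acc / n_avg, resolution = sp$resolution)
}
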
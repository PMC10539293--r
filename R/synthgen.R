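#' Synthetic FPVS study configuration
#'
#' Parameters of the synthetic EEG generator. Defaults emulate the study
#' conditions of the familiar/unfamiliar face-identity paradigm: 14
#' participants, 8 sequences per condition, 74 s sequences (2 s fade-in/out)
#' at 512 Hz, a 6 Hz base response and a 1.2 Hz oddball response whose
#' amplitude in the unfamiliar condition is `oddball_ratio` (0.29) times the
#' familiar amplitude, occipito-temporal topography, and 1/f background
#' noise.
#'
#' Amplitudes are summed-harmonic amplitudes in microvolts at topography
#' weight 1 (see [oddball_kernel()]): the familiar default of 0.86 uV matches
#' the group occipito-temporal mean reported for the paradigm, and
#' `noise_scale` is the broadband RMS of the 1/f background per channel.
#'
#' @param n_participants number of participants.
#' @param channel_labels 10-5-style channel names; must include the 22
#'   region-of-interest channels of [roi_layout()].
#' @param rate sample rate, Hz.
#' @param n_sequences_per_condition sequences per condition per participant.
#' @param sequence_duration stimulation duration, s (includes the fades).
#' @param fade_in,fade_out linear amplitude ramp durations, s.
#' @param pad_s noise-only context recorded before/after the stimulation
#'   sequence, s (gives the segmentation its -2 s pre-onset support).
#' @param base_freq,oddball_freq stimulation and oddball frequencies, Hz.
#'   `base_freq / oddball_freq` must be an integer.
#' @param base_amp,oddball_amp_familiar summed-harmonic amplitudes, uV.
#' @param oddball_ratio unfamiliar amplitude as a fraction of familiar.
#' @param noise_exponent alpha of the 1/f^alpha amplitude-spectrum noise.
#' @param noise_scale broadband noise RMS per channel, uV.
#' @param line_noise_amp 50 Hz line-noise amplitude, uV (0 = off).
#' @param participant_gain_sd SD of the per-participant lognormal gain.
#' @param seed master seed; all per-recording seeds derive from it.
#' @return An object of class `fpvs_generator_config` (a validated list).
#' @export
generator_config <- function(n_participants = 14,
                             channel_labels = default_channels(),
                             rate = 512,
                             n_sequences_per_condition = 8,
                             sequence_duration = 74,
                             fade_in = 2, fade_out = 2, pad_s = 2,
                             base_freq = 6.0, oddball_freq = 1.2,
                             base_amp = 2.0, oddball_amp_familiar = 0.86,
                             oddball_ratio = 0.29,
                             noise_exponent = 1, noise_scale = 0.15,
                             line_noise_amp = 0,
                             participant_gain_sd = 0.4,
                             seed = 1L) {
  cfg <- list(n_participants = n_participants,
              channel_labels = channel_labels,
              n_channels = length(channel_labels),
              rate = rate,
              n_sequences_per_condition = n_sequences_per_condition,
              sequence_duration = sequence_duration,
              fade_in = fade_in, fade_out = fade_out, pad_s = pad_s,
              base_freq = base_freq, oddball_freq = oddball_freq,
              base_amp = base_amp,
              oddball_amp_familiar = oddball_amp_familiar,
              oddball_ratio = oddball_ratio,
              noise_exponent = noise_exponent, noise_scale = noise_scale,
              line_noise_amp = line_noise_amp,
              participant_gain_sd = participant_gain_sd,
              seed = as.integer(seed))
  class(cfg) <- "fpvs_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  amps <- c(cfg$base_amp, cfg$oddball_amp_familiar, cfg$noise_scale,
            cfg$line_noise_amp)
  if (any(amps < 0)) stopf("all amplitudes must be >= 0")
  if (cfg$oddball_ratio < 0 || cfg$oddball_ratio > 1)
    stopf("oddball_ratio must lie in [0, 1]")
  ratio <- cfg$base_freq / cfg$oddball_freq
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("base_freq / oddball_freq must be an integer (got %.4f)", ratio)
  # Nyquist check against the highest frequency actually generated
  fmax <- 0
  if (cfg$base_amp > 0) fmax <- max(fmax, 10 * cfg$base_freq)
  if (cfg$oddball_amp_familiar > 0) fmax <- max(fmax, 6 * cfg$oddball_freq)
  if (cfg$line_noise_amp > 0) fmax <- max(fmax, 50)
  if (cfg$rate <= 2 * fmax)
    stopf("rate (%g Hz) must exceed twice the highest generated frequency (%g Hz)",
          cfg$rate, fmax)
  if (cfg$sequence_duration <= cfg$fade_in + cfg$fade_out)
    stopf("sequence_duration must exceed the fades")
  missing_roi <- setdiff(unlist(roi_layout()), cfg$channel_labels)
  if (length(missing_roi))
    stopf("channel_labels must include the ROI channels; missing: %s",
          paste(missing_roi, collapse = ", "))
  invisible(cfg)
}

#' Default synthetic montage
#'
#' The 22 region-of-interest channels (bilateral occipito-temporal and
#' middle-occipital groups) plus 10 standard midline/lateral 10-5 sites.
#'
#' @return character vector of 32 channel labels.
#' @export
default_channels <- function() {
  c(unlist(roi_layout()[c("OT_left", "OT_right", "MO")], use.names = FALSE),
    c("Fz", "Cz", "Pz", "CPz", "C3", "C4", "F3", "F4", "T7", "T8"))
}

#' Topography weights for the synthetic responses
#'
#' Per-channel gains in [0, 1] for the base response (middle-occipital peak)
#' and the oddball response (bilateral occipito-temporal peak, with an
#' optional right-hemisphere gain multiplier for the oddball response).
#'
#' @param channel_labels channel names.
#' @param right_gain multiplier applied to right occipito-temporal oddball
#'   weights (capped at 1). The paradigm gives no quantitative
#'   right-lateralization magnitude, so the default is neutral (1).
#' @return list with named numeric vectors `base` and `oddball`.
#' @export
topography_weights <- function(channel_labels, right_gain = 1) {
  rois <- roi_layout()
  base <- setNames(rep(0.2, length(channel_labels)), channel_labels)
  base[intersect(rois$MO, channel_labels)] <- 1.0
  base[intersect(rois$OT, channel_labels)] <- 0.5
  odd <- setNames(rep(0.05, length(channel_labels)), channel_labels)
  odd[intersect(rois$MO, channel_labels)] <- 0.15
  odd[intersect(rois$OT_left, channel_labels)] <- 1.0
  odd[intersect(rois$OT_right, channel_labels)] <- pmin(1, 1.0 * right_gain)
  w <- list(base = base, oddball = odd)
  if (any(unlist(w) < 0 | unlist(w) > 1)) stopf("weights must lie in [0, 1]")
  w
}

# 1/f^alpha noise, channels x n, via spectral synthesis. `alpha` is the
# amplitude-spectrum exponent above the 1 Hz low-frequency knee; below the
# knee the spectrum is flat, as in resting EEG (an unflattened 1/f continued
# to DC would concentrate most variance in slow drift, whose spectral
# leakage would dominate the noise bins around the oddball fundamental in
# finite windows). Synthesis runs on a grid twice the requested length
# and keeps the first half, so the output is not periodic over the record
# (periodic noise would correlate neighboring frequency bins of cropped
# analysis windows, which continuous EEG noise does not). Each channel is
# scaled to the requested broadband RMS.
make_noise <- function(n_channels, n, rate, alpha, rms) {
  if (rms <= 0 || n_channels == 0) return(matrix(0, n_channels, n))
  ng <- 2L * n
  freqs <- seq_len(floor((ng - 1) / 2)) * rate / ng
  shape <- pmax(freqs, 1)^(-alpha)
  co <- matrix(complex(
    real = rnorm(length(freqs) * n_channels),
    imaginary = rnorm(length(freqs) * n_channels)), ncol = n_channels)
  co <- co * shape
  spec <- matrix(0i, ng, n_channels)
  spec[2:(length(freqs) + 1), ] <- co
  spec[ng - seq_along(freqs) + 1, ] <- Conj(co)
  x <- Re(mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE] / ng
  x <- t(x)
  sc <- rms / sqrt(rowMeans(x^2))
  x * sc
}

#' Generate one synthetic stimulation sequence
#'
#' Builds one recording: 1/f background noise plus a base-frequency kernel
#' train and an oddball-frequency kernel train (biphasic kernel, lobes near
#' 242 and 362 ms after oddball onset), with the signal amplitude ramped
#' linearly over the fade-in and fade-out. The recording includes `pad_s`
#' seconds of noise-only context before and after the stimulation sequence
#' and carries an event marker at the stimulation onset.
#'
#' @param config a [generator_config()].
#' @param topo topography weights from [topography_weights()]; defaults to
#'   the standard layout for `config$channel_labels`.
#' @param condition "familiar" or "unfamiliar".
#' @param seed seed for this sequence's noise (defaults to `config$seed`).
#' @param gain multiplicative participant gain applied to both responses.
#' @param participant_id label stored on the recording.
#' @return An [recording()] object of duration
#'   `sequence_duration + 2 * pad_s`.
#' @export
generate_sequence <- function(config, topo = NULL,
                              condition = c("familiar", "unfamiliar"),
                              seed = NULL, gain = 1,
                              participant_id = NA_character_) {
  stopifnot(inherits(config, "fpvs_generator_config"))
  if (!is.character(condition) ||
      !condition[1] %in% c("familiar", "unfamiliar"))
    stopf("unknown condition label: %s", paste(condition[1]))
  condition <- condition[1]
  seed <- seed %||% config$seed
  ok <- oddball_kernel(fundamental = config$oddball_freq)
  bk <- base_kernel(fundamental = config$base_freq)
  if (ok$support_end_s > 1 / config$oddball_freq)
    stopf("oddball kernel support (%.3f s) exceeds one oddball cycle (%.3f s)",
          ok$support_end_s, 1 / config$oddball_freq)
  rate <- config$rate
  n <- round((config$sequence_duration + 2 * config$pad_s) * rate)
  t_rec <- (0:(n - 1)) / rate
  ts <- t_rec - config$pad_s                      # stimulation-local time
  in_stim <- ts >= 0 & ts < config$sequence_duration
  ramp <- numeric(n)
  ramp[in_stim] <- pmin(1,
    pmin(ts[in_stim] / config$fade_in,
         (config$sequence_duration - ts[in_stim]) / config$fade_out))
  odd_amp <- config$oddball_amp_familiar *
    if (condition == "familiar") 1 else config$oddball_ratio
  base_sig <- if (config$base_amp > 0)
    config$base_amp * gain * eval_kernel(bk, ts) * ramp else numeric(n)
  odd_sig <- if (odd_amp > 0)
    odd_amp * gain * eval_kernel(ok, ts) * ramp else numeric(n)
  w <- topo %||% topography_weights(config$channel_labels)
  x <- with_seed(seed,
    make_noise(config$n_channels, n, rate, config$noise_exponent,
               config$noise_scale))
  if (config$base_amp > 0)
    x <- x + outer(unname(w$base[config$channel_labels]), base_sig)
  if (odd_amp > 0)
    x <- x + outer(unname(w$oddball[config$channel_labels]), odd_sig)
  if (config$line_noise_amp > 0)
    x <- x + matrix(config$line_noise_amp * sin(2 * pi * 50 * t_rec),
                    config$n_channels, n, byrow = TRUE)
  recording(x, rate, config$channel_labels,
            events = data.frame(time = config$pad_s,
                                code = if (condition == "familiar") 1L else 2L),
            condition = condition, participant_id = participant_id)
}

#' Index of a synthetic study
#'
#' Lays out one row per recording (participant x condition x sequence) with
#' the derived seed and the participant's lognormal gain, without generating
#' any data. [generate_study()] materializes the recordings;
#' [run_study()] streams them one at a time from the same index.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns participant, condition, sequence, seed,
#'   gain.
#' @export
study_index <- function(config) {
  stopifnot(inherits(config, "fpvs_generator_config"))
  gains <- with_seed(derive_seed(config$seed, 777),
                     rlnorm(config$n_participants, 0,
                            config$participant_gain_sd))
  idx <- expand.grid(sequence = seq_len(config$n_sequences_per_condition),
                     condition = c("familiar", "unfamiliar"),
                     participant = seq_len(config$n_participants),
                     stringsAsFactors = FALSE)
  idx <- idx[, c("participant", "condition", "sequence")]
  idx$participant_id <- sprintf("P%02d", idx$participant)
  idx$seed <- mapply(function(p, c, s)
    derive_seed(config$seed, p, match(c, c("familiar", "unfamiliar")), s),
    idx$participant, idx$condition, idx$sequence)
  idx$gain <- gains[idx$participant]
  rownames(idx) <- NULL
  idx
}

#' Generate a full synthetic study
#'
#' One recording per participant x condition x sequence. Each participant has
#' a single multiplicative lognormal gain applied to both conditions; all
#' seeds derive deterministically from the master seed, so identical configs
#' give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param topo optional [topography_weights()].
#' @return list with `index` (see [study_index()]) and `recordings` (list of
#'   [recording()] objects, parallel to the index rows).
#' @export
generate_study <- function(config, topo = NULL) {
  idx <- study_index(config)
  recs <- lapply(seq_len(nrow(idx)), function(i)
    generate_sequence(config, topo, idx$condition[i], seed = idx$seed[i],
                      gain = idx$gain[i],
                      participant_id = idx$participant_id[i]))
  list(index = idx, recordings = recs)
}

# ---- synthetic face image sets ----

#' Synthetic face-image set configuration
#'
#' @param n_images number of images.
#' @param width,height image size in pixels (stimulus convention: 200 x 250).
#' @param mean_luminance target mean pixel intensity in [0, 1].
#' @param rms_contrast target pixel-intensity SD.
#' @param spectral_slope target log-log radial amplitude slope magnitude
#'   (amplitude ~ frequency^-slope); natural images sit near 1.
#' @param landmark_jitter SD of the landmark position jitter, pixels.
#' @param seed master seed.
#' @return An object of class `fpvs_imageset_config`.
#' @export
image_set_config <- function(n_images = 20, width = 200, height = 250,
                             mean_luminance = 0.5, rms_contrast = 0.15,
                             spectral_slope = 1, landmark_jitter = 3,
                             seed = 1L) {
  if (width <= 0 || height <= 0) stopf("width and height must be positive")
  if (rms_contrast < 0) stopf("rms_contrast must be >= 0")
  structure(list(n_images = n_images, width = width, height = height,
                 mean_luminance = mean_luminance, rms_contrast = rms_contrast,
                 spectral_slope = spectral_slope,
                 landmark_jitter = landmark_jitter, seed = as.integer(seed)),
            class = "fpvs_imageset_config")
}

# One 1/f^slope noise image, standardized to (mean, sd) then clipped to [0,1].
make_noise_image <- function(h, w, slope, mean_lum, contrast) {
  if (contrast == 0) return(matrix(mean_lum, h, w))
  kx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)
  ky <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)
  r <- sqrt(outer(ky^2, kx^2, "+"))
  shape <- ifelse(r > 0, pmax(r, 1)^(-slope), 0)
  wn <- matrix(rnorm(h * w), h, w)
  f <- fft(wn) * shape
  img <- Re(fft(f, inverse = TRUE)) / (h * w)
  img <- (img - mean(img)) / sd(img) * contrast + mean_lum
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic face-image set
#'
#' Produces grayscale 1/f-noise images with controlled mean luminance, RMS
#' contrast and radial-spectrum slope, together with a landmark table (nose
#' tip, pupils; origin top-left, x rightward) and an elliptical face mask per
#' image. These are synthetic stand-ins with face-like image statistics and
#' geometry; they contain no face content.
#'
#' @param config an [image_set_config()].
#' @param dir optional output directory; if given, images and masks are
#'   written as PNG plus a `landmarks.tsv` table.
#' @return list with `images` (list of [image_record()]s) and `landmarks`
#'   (data.frame).
#' @export
generate_face_image_set <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fpvs_imageset_config"))
  w <- config$width; h <- config$height
  cy <- 0.5 * h; cx <- 0.5 * w
  mask <- outer(((seq_len(h) - cy) / (0.36 * h))^2,
                ((seq_len(w) - cx) / (0.32 * w))^2, "+") <= 1
  imgs <- vector("list", config$n_images)
  lm <- data.frame(image_id = sprintf("img%03d", seq_len(config$n_images)),
                   nose_x = NA_real_, nose_y = NA_real_,
                   lpupil_x = NA_real_, lpupil_y = NA_real_,
                   rpupil_x = NA_real_, rpupil_y = NA_real_)
  for (i in seq_len(config$n_images)) {
    px <- with_seed(derive_seed(config$seed, 555, i),
                    make_noise_image(h, w, config$spectral_slope,
                                     config$mean_luminance,
                                     config$rms_contrast))
    jit <- with_seed(derive_seed(config$seed, 556, i),
                     rnorm(6, 0, config$landmark_jitter))
    nose <- c(0.5 * w, 0.55 * h) + jit[1:2]
    lp <- c(0.32 * w, 0.38 * h) + jit[3:4]
    rp <- c(0.68 * w, 0.38 * h) + jit[5:6]
    clampx <- function(v) pmin(w, pmax(1, v))
    clampy <- function(v) pmin(h, pmax(1, v))
    lm[i, 2:7] <- c(clampx(nose[1]), clampy(nose[2]), clampx(lp[1]),
                    clampy(lp[2]), clampx(rp[1]), clampy(rp[2]))
    imgs[[i]] <- image_record(
      px,
      landmarks = list(nose = c(lm$nose_x[i], lm$nose_y[i]),
                       left_pupil = c(lm$lpupil_x[i], lm$lpupil_y[i]),
                       right_pupil = c(lm$rpupil_x[i], lm$rpupil_y[i])),
      mask = mask)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(config$n_images)) {
      png::writePNG(imgs[[i]]$pixels,
                    file.path(dir, paste0(lm$image_id[i], ".png")))
      png::writePNG(mask * 1,
                    file.path(dir, paste0(lm$image_id[i], "_mask.png")))
    }
    write.table(lm, file.path(dir, "landmarks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(images = imgs, landmarks = lm)
}
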
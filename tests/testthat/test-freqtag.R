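test_that("integer-cycle cropping reproduces the standard 83-cycle epoch", {
  rec <- generate_sequence(generator_config(noise_scale = 0, seed = 1),
                           condition = "familiar")
  seg <- preprocess_recording(rec)[[1]]
  ep <- crop_integer_cycles(seg)
  expect_equal(ep$n_cycles, 83)
  expect_equal(ep$duration, 69.17, tolerance = 0.005)
  sp <- amplitude_spectrum(ep)
  expect_lt(abs(sp$resolution - 0.0145), 5e-5)
  # every oddball harmonic is bin-centered in the integer-cycle epoch
  for (k in 1:50) {
    f <- k * 1.2
    kb <- round(f / sp$resolution) + 1
    expect_lt(abs(sp$freqs[kb] - f), sp$resolution / 2)
  }
})

test_that("cropping handles short spans and refuses impossible requests", {
  rec <- signal_recording(matrix(rnorm(64 * 14), 1), 64, event_s = 0)
  seg <- segment_sequences(rec, pre = 0, post = 14)[[1]]
  ep <- crop_integer_cycles(seg, oddball_freq = 1, start = 0, n_cycles = 10)
  expect_equal(ep$duration, 10)
  expect_equal(ep$n_cycles, 10)
  expect_error(crop_integer_cycles(seg, oddball_freq = 1.2, start = 0,
                                   n_cycles = 200),
               "exceed")
  epm <- crop_integer_cycles(seg, oddball_freq = 1, start = 2,
                             n_cycles = "max")
  expect_equal(epm$n_cycles, 12)
})

test_that("amplitude spectra are normalized to sinusoid peak amplitude", {
  rate <- 64
  n <- rate * 10
  tt <- (0:(n - 1)) / rate
  ep <- structure(list(samples = rbind(sin(2 * pi * 1.2 * tt), numeric(n)),
                       rate = rate, channel_labels = c("s", "z")),
                  class = "fpvs_epoch")
  sp <- amplitude_spectrum(ep)
  k <- round(1.2 / sp$resolution) + 1
  expect_equal(unname(sp$amplitude[1, k]), 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[1, -k]), 1e-9)
  expect_true(all(sp$amplitude[2, ] == 0))
  expect_equal(sp$resolution, 1 / 10)
})

test_that("SNR, baseline subtraction and z-scores follow their definitions", {
  nb <- neighbor_spec()
  expect_equal(nb$offsets, c(-25:-2, 2:25))
  amp <- rep(2, 200); amp[100] <- 10
  sp <- synth_spectrum(amp, 0.1)
  snr <- snr_spectrum(sp, nb)
  expect_equal(snr$amplitude[1, 100], 5)
  expect_equal(snr$amplitude[1, 150], 1)    # flat region
  expect_true(all(is.na(snr$amplitude[1, 1:10])))  # edge bins undefined
  sbl <- baseline_subtract(sp, nb)
  expect_equal(sbl$amplitude[1, 100], 8)
  # z: construct neighbors with known mean/sd
  amp2 <- rep(c(1, 3), 100)                 # mean 2, sd ~1.0025
  sp2 <- synth_spectrum(amp2, 0.1)
  k <- 101
  nbr <- amp2[k + nb$offsets]
  z <- zscore_bin(sp2, sp2$freqs[k], nb)
  expect_equal(unname(z), (amp2[k] - mean(nbr)) / sd(nbr), tolerance = 1e-12)
  amp3 <- amp2; amp3[k] <- mean(nbr) + 2 * sd(nbr)
  expect_equal(unname(zscore_bin(synth_spectrum(amp3, 0.1), sp2$freqs[k], nb)),
               2, tolerance = 1e-12)
})

test_that("noise-only spectra calibrate SNR to 1, SBL to 0 and z to its null rate", {
  nb <- neighbor_spec()
  cfg <- noise_cfg(seed = 41, noise_exponent = 1)
  n_sim <- 200
  pick <- function(sp, f) round(f / (1 / 25)) + 1   # 30 cycles -> 25 s
  snr_at <- sbl_at <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    rec <- generate_sequence(cfg, condition = "familiar",
                             seed = fpvstag:::derive_seed(41, s))
    ep <- crop_integer_cycles(as_segment(rec), start = 2, n_cycles = 30)
    ep$samples <- ep$samples["P7", , drop = FALSE]
    ep$channel_labels <- "P7"
    sp <- amplitude_spectrum(ep)
    k <- pick(sp, 3.6)
    snr_at[s] <- snr_spectrum(sp, nb)$amplitude[1, k]
    sbl_at[s] <- baseline_subtract(sp, nb)$amplitude[1, k]
  }
  expect_equal(mean(snr_at), 1, tolerance = 0.05)
  expect_lt(abs(mean(sbl_at)), 2 * sd(sbl_at) / sqrt(n_sim))
})

test_that("injected signal amplitude is recovered by baseline subtraction", {
  # study-default noise and timing, 8 sequences averaged; recovery is
  # measured over the occipito-temporal channels (topography weight 1,
  # without average re-referencing, which would rescale the topography)
  nb <- neighbor_spec()
  cfg <- generator_config(participant_gain_sd = 0, seed = 6)
  acc <- NULL
  for (s in 1:8) {
    rec <- generate_sequence(cfg, condition = "familiar",
                             seed = fpvstag:::derive_seed(6, s))
    ep <- crop_integer_cycles(as_segment(rec), start = 2, n_cycles = 83)
    sp <- amplitude_spectrum(ep)
    acc <- if (is.null(acc)) sp$amplitude else acc + sp$amplitude
  }
  sp$amplitude <- acc / 8
  hs <- harmonic_set(1.2, c(1.2, 2.4, 3.6, 4.8, 7.2))
  got <- summed_response(baseline_subtract(sp, nb), hs)
  expect_equal(mean(got[roi_layout()$OT]), 0.86, tolerance = 0.10)
})

test_that("harmonic selection walks consecutively and excludes base multiples", {
  nb <- neighbor_spec()
  res <- 0.0145
  freqs <- (0:6000) * res
  set.seed(13)
  base_noise <- abs(rnorm(6001, 0, 0.002)) + 0.01
  amp <- base_noise
  put <- function(a, f, v) { a[round(f / res) + 1] <- v; a }
  for (f in c(1.2, 2.4, 3.6, 4.8, 7.2)) amp <- put(amp, f, 0.2)
  for (f in seq(6, 60, 6)) amp <- put(amp, f, 0.5)
  sp <- synth_spectrum(amp, res)
  hs <- select_harmonics(sp, 1.2, exclude_multiples_of = 6, f_max = 40,
                         nb = nb)
  expect_equal(hs$harmonics, c(1.2, 2.4, 3.6, 4.8, 7.2))
  expect_equal(hs$excluded, 6)
  hsb <- select_harmonics(sp, 6, f_max = 80, nb = nb)
  expect_equal(hsb$harmonics, seq(6, 60, 6))
  # signal at the fundamental only
  sp1 <- synth_spectrum(put(base_noise, 1.2, 0.2), res)
  hs1 <- select_harmonics(sp1, 1.2, exclude_multiples_of = 6, f_max = 40,
                          nb = nb)
  expect_equal(hs1$harmonics, 1.2)
})

test_that("summed responses add SBL values and scale with input amplitude", {
  res <- 0.1
  amp <- rep(0, 400)
  hs <- harmonic_set(1.2, c(1.2, 2.4, 3.6, 4.8, 7.2))
  ks <- round(hs$harmonics / res) + 1
  amp[ks] <- c(0.4, 0.3, 0.2, 0.1, 0.0)
  sp <- synth_spectrum(amp, res)
  sp$kind <- "sbl"
  expect_equal(unname(summed_response(sp, hs)), 1.0)
  sp0 <- synth_spectrum(rep(0, 400), res); sp0$kind <- "sbl"
  expect_equal(unname(summed_response(sp0, hs)), 0)
  # SNR is invariant under global rescaling; SBL scales linearly
  set.seed(2)
  raw <- synth_spectrum(abs(rnorm(400)) + 0.5, res)
  raw3 <- raw; raw3$amplitude <- 3 * raw$amplitude
  nb <- neighbor_spec(5, 1)
  expect_equal(snr_spectrum(raw3, nb)$amplitude,
               snr_spectrum(raw, nb)$amplitude, tolerance = 1e-12)
  expect_equal(baseline_subtract(raw3, nb)$amplitude,
               3 * baseline_subtract(raw, nb)$amplitude, tolerance = 1e-12)
})

test_that("summed ROI z-score behaves at its fixed points and under strong signal", {
  nb <- neighbor_spec()
  hs <- harmonic_set(1.2, c(1.2, 2.4, 3.6, 4.8, 7.2))
  res <- 0.04
  flat <- synth_spectrum(rep(2, 2000), res)
  z0 <- summed_zscore(flat, hs, nb)
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  expect_error(summed_zscore(flat, hs, nb, channels = "P7"), "missing")
  # raising each harmonic bin by 5 neighbor-SD forces detection
  set.seed(77)
  for (run in 1:20) {
    amp <- abs(rnorm(2000, 1, 0.2))
    ks <- round(hs$harmonics / res) + 1
    sdn <- sd(amp[ks[1] + nb$offsets])
    amp[ks] <- amp[ks] + 5 * sdn
    z <- summed_zscore(synth_spectrum(amp, res), hs, nb)
    expect_gt(z$z, 1.64)
  }
})

test_that("bin-level z false-positive rate is calibrated under pure noise", {
  nb <- neighbor_spec()
  cfg <- noise_cfg(seed = 51)
  hits <- logical(0)
  batch <- 0
  while (length(hits) < 2000) {
    batch <- batch + 1
    sp <- noise_batch_spectra(cfg, n_avg = 8,
                              seed = fpvstag:::derive_seed(51, batch))
    z <- zscore_bin(synth_spectrum(sp$amplitude, sp$resolution), 3.6, nb)
    hits <- c(hits, unname(z) > 1.64)   # one simulation per channel
  }
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("ROI aggregation averages member channels and the whole montage", {
  vals <- setNames(rep(1, 32), default_channels())
  agg <- roi_aggregate(vals)
  expect_equal(unname(agg["OT"]), 1)
  rois <- roi_layout()
  expect_length(rois$OT, 10)
  expect_length(rois$MO, 12)
  vals[rois$OT_left] <- 0
  vals[rois$OT_right] <- 2
  agg <- roi_aggregate(vals)
  expect_equal(unname(agg["OT"]), 1)
  expect_equal(unname(agg["OT_left"]), 0)
  expect_error(roi_aggregate(vals[-1]), "missing")
})
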
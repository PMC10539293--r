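test_that("generation is deterministic and respects degenerate amplitudes", {
  cfg <- short_cfg(seed = 5)
  r1 <- generate_sequence(cfg, condition = "familiar", seed = 99)
  r2 <- generate_sequence(cfg, condition = "familiar", seed = 99)
  expect_identical(r1$samples, r2$samples)
  expect_error(generate_sequence(cfg, condition = "novel"),
               "unknown condition")
  cfg0 <- short_cfg(base_amp = 0, oddball_amp_familiar = 0, noise_scale = 0)
  r0 <- generate_sequence(cfg0, condition = "unfamiliar")
  expect_true(all(r0$samples == 0))
  expect_equal(r0$events$time, 2)
  expect_equal(ncol(r0$samples) / r0$rate, 29 + 4)  # padded by 2 s each side
})

test_that("with noise off, spectral energy sits only on oddball-frequency multiples", {
  cfg <- short_cfg(noise_scale = 0, rate = 256)
  rec <- generate_sequence(cfg, condition = "familiar")
  ep <- crop_integer_cycles(as_segment(rec), start = 2, n_cycles = 30)
  sp <- amplitude_spectrum(ep)
  amp <- sp$amplitude["P7", ]
  k <- round(sp$freqs / 1.2)
  on_harm <- abs(sp$freqs - k * 1.2) < sp$resolution / 2 & k > 0
  expect_gt(max(amp[on_harm]), 0.01)
  expect_lt(max(amp[!on_harm]), 1e-10 * max(amp))
})

test_that("generated oddball harmonics match an independently constructed train", {
  cfg <- short_cfg(noise_scale = 0, base_amp = 0, rate = 256, seed = 2)
  rec <- generate_sequence(cfg, condition = "familiar")
  ep <- crop_integer_cycles(as_segment(rec), start = 2, n_cycles = 30)
  # oracle: explicit cosine sum from the kernel's published parameters,
  # transformed with stats::fft over the same window
  k <- oddball_kernel()
  n <- ncol(ep$samples)
  tt <- 2 + (0:(n - 1)) / 256          # crop starts 2 s into stimulation
  train <- 0.86 * Reduce(`+`, lapply(seq_along(k$freqs), function(h)
    k$amp[h] * cos(2 * pi * k$freqs[h] * tt + k$phase[h])))
  oracle <- 2 * Mod(stats::fft(train)) / n
  got <- ep$samples["P7", ]            # oddball topography weight 1 at P7
  got_amp <- 2 * Mod(stats::fft(got)) / n
  bins <- round(k$freqs * n / 256) + 1
  expect_equal(got_amp[bins], oracle[bins], tolerance = 1e-9)
  # condition scaling: unfamiliar = 0.29 x familiar
  rec_u <- generate_sequence(cfg, condition = "unfamiliar")
  ep_u <- crop_integer_cycles(as_segment(rec_u), start = 2, n_cycles = 30)
  amp_u <- 2 * Mod(stats::fft(ep_u$samples["P7", ])) / n
  expect_equal(amp_u[bins], 0.29 * got_amp[bins], tolerance = 1e-9)
})

test_that("1/f noise recovers its spectral exponent from the average spectrum", {
  cfg <- generator_config(base_amp = 0, oddball_amp_familiar = 0,
                          noise_scale = 5, noise_exponent = 1,
                          participant_gain_sd = 0, seed = 31)
  rec <- generate_sequence(cfg, condition = "familiar")
  ep <- crop_integer_cycles(as_segment(rec), start = 2, n_cycles = 83)
  sp <- amplitude_spectrum(ep)
  prof <- colMeans(sp$amplitude)        # average across 32 channels
  sel <- sp$freqs >= 1 & sp$freqs <= 40
  fit <- coef(lm(log(prof[sel]) ~ log(sp$freqs[sel])))[2]
  expect_lt(abs(fit - (-1)), 0.15)
})

test_that("study layout gives participants x conditions x sequences recordings", {
  idx <- study_index(generator_config())
  expect_equal(nrow(idx), 14 * 2 * 8)
  expect_equal(sum(idx$participant_id == "P01"), 16)
  cfg <- short_cfg(n_participants = 1, n_sequences_per_condition = 1,
                   rate = 256)
  st <- generate_study(cfg)
  expect_length(st$recordings, 2)
  expect_setequal(st$index$condition, c("familiar", "unfamiliar"))
  st2 <- generate_study(cfg)
  expect_identical(st$recordings[[1]]$samples, st2$recordings[[1]]$samples)
  # one gain per participant, shared across that participant's recordings
  expect_length(unique(st$index$gain), 1)
})

test_that("amplitude scaling propagates linearly to the generated signal", {
  cfg1 <- short_cfg(noise_scale = 0, rate = 256)
  cfg2 <- short_cfg(noise_scale = 0, rate = 256, base_amp = 4,
                    oddball_amp_familiar = 1.72)
  r1 <- generate_sequence(cfg1, condition = "familiar")
  r2 <- generate_sequence(cfg2, condition = "familiar")
  expect_equal(r2$samples, 2 * r1$samples, tolerance = 1e-12)
})

test_that("synthetic image sets match their configured statistics", {
  cfg <- image_set_config(n_images = 6, mean_luminance = 0.5,
                          rms_contrast = 0.12, spectral_slope = 1, seed = 9)
  s <- generate_face_image_set(cfg)
  st <- image_set_stats(s$images)
  expect_equal(mean(st$per_image$luminance), 0.5, tolerance = 0.01)
  expect_equal(mean(st$per_image$contrast), 0.12, tolerance = 0.12 * 0.02)
  # white images fit a flat radial profile
  cfg0 <- image_set_config(n_images = 4, spectral_slope = 0, seed = 10)
  s0 <- generate_face_image_set(cfg0)
  prof <- rowMeans(vapply(s0$images, radial_amplitude_profile, numeric(100)))
  expect_lt(abs(loglog_slope(prof)), 0.1)
  # zero contrast collapses to a constant image
  cfgc <- image_set_config(n_images = 1, rms_contrast = 0, seed = 11)
  img <- generate_face_image_set(cfgc)$images[[1]]
  expect_true(all(img$pixels == 0.5))
  # jitter-free landmarks are symmetric: orientation ratio 1
  cfgj <- image_set_config(n_images = 1, landmark_jitter = 0, seed = 12)
  expect_equal(orientation_ratio(generate_face_image_set(cfgj)$images[[1]]),
               1.0, tolerance = 1e-12)
})

test_that("image sets round-trip through PNG files and a landmark table", {
  dir <- withr::local_tempdir()
  cfg <- image_set_config(n_images = 2, seed = 3)
  s <- generate_face_image_set(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "img001.png")))
  expect_true(file.exists(file.path(dir, "img001_mask.png")))
  lm <- read.delim(file.path(dir, "landmarks.tsv"))
  expect_equal(nrow(lm), 2)
  img <- read_image(file.path(dir, "img001.png"),
                    mask_path = file.path(dir, "img001_mask.png"))
  expect_equal(dim(img$pixels), c(250, 200))
  expect_equal(img$pixels, s$images[[1]]$pixels, tolerance = 1 / 255)
})
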
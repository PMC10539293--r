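make_td_seg <- function(x, rate) {
  rec <- signal_recording(x, rate, event_s = 0)
  segment_sequences(rec, pre = 0, post = ncol(rec$samples) / rate)[[1]]
}

test_that("waveform preparation low-passes at 30 Hz and crops integer cycles", {
  rate <- 256
  n <- rate * 15
  tt <- (0:(n - 1)) / rate
  seg <- make_td_seg(rbind(sin(2 * pi * 40 * tt), sin(2 * pi * 1 * tt)), rate)
  ep <- prepare_waveforms(seg, start = 0, n_cycles = 12)
  expect_equal(ep$duration, 10)
  expect_lt(fft_amp_at(ep$samples[1, ], rate, 40), 0.5)
  expect_equal(fft_amp_at(ep$samples[2, ], rate, 1), 1, tolerance = 0.02)
})

test_that("base-harmonic notches remove 6 Hz multiples but spare oddball harmonics", {
  rate <- 256
  n <- rate * 25
  tt <- (0:(n - 1)) / rate
  seg <- make_td_seg(rbind(sin(2 * pi * 6 * tt), sin(2 * pi * 7.2 * tt),
                           sin(2 * pi * 24 * tt), numeric(n)), rate)
  out <- remove_base_harmonics(seg)
  expect_lt(fft_amp_at(out$samples[1, ], rate, 6), 0.1)
  expect_gt(fft_amp_at(out$samples[2, ], rate, 7.2), 0.98)
  expect_lt(fft_amp_at(out$samples[3, ], rate, 24), 0.1)
  expect_true(all(out$samples[4, ] == 0))
})

test_that("five-cycle epochs average to the oddball kernel on a pure train", {
  # rate chosen so one oddball cycle is an integer sample count: epochs are
  # exactly aligned and the average must equal the train to float precision
  rate <- 300
  k <- oddball_kernel()
  n <- round(30 / 1.2 * rate)          # 30 cycles from 2 s
  tt <- 2 + (0:(n - 1)) / rate
  train <- Reduce(`+`, lapply(seq_along(k$freqs), function(h)
    k$amp[h] * cos(2 * pi * k$freqs[h] * tt + k$phase[h])))
  ep <- structure(list(samples = matrix(train, 1), rate = rate,
                       channel_labels = "P7"), class = "fpvs_epoch")
  avg <- epoch_and_average(ep, crop_start_s = 2)
  expect_equal(diff(range(avg$time_ms)) + 1000 / rate, 833, tolerance = 2)
  # oracle: the same cosine sum evaluated on the epoch time axis, baselined
  onset_s <- ceiling((2 + 1 / 6) / (1 / 1.2)) / 1.2
  t_axis <- onset_s + avg$time_ms / 1000
  oracle <- Reduce(`+`, lapply(seq_along(k$freqs), function(h)
    k$amp[h] * cos(2 * pi * k$freqs[h] * t_axis + k$phase[h])))
  bl <- avg$time_ms <= 0
  oracle <- oracle - mean(oracle[bl])
  expect_equal(as.numeric(avg$waveform[1, ]), oracle, tolerance = 1e-6)
  expect_equal(avg$n_epochs, floor((30 * (1 / 1.2) - 5 / 6) / (1 / 1.2)))
  # constant input is annihilated by baseline correction
  epc <- ep; epc$samples[] <- 3.7
  avgc <- epoch_and_average(epc, crop_start_s = 2)
  expect_lt(max(abs(avgc$waveform)), 1e-12)
})

test_that("paired cluster test finds no clusters when conditions are identical", {
  set.seed(1)
  tm <- seq(-167, 667, length.out = 215)
  a <- matrix(rnorm(10 * 215), 10)
  res <- cluster_test_paired(a, a, tm, n_perm = 200)
  expect_equal(nrow(res$clusters), 0)
  expect_length(res$null, 200)
})

test_that("degenerate zero-variance waveforms are flagged, not NaN", {
  tm <- seq(0, 667, length.out = 172)
  x <- matrix(5, 8, 172)               # constant offset, zero variance
  expect_warning(res <- cluster_test_vs_zero(x, tm, n_perm = 50), "small")
  expect_true(all(is.finite(res$t)))
  expect_equal(res$degenerate_points, 172)
  expect_equal(nrow(res$clusters), 0)
})

test_that("paired cluster test is symmetric and scale-invariant", {
  set.seed(7)
  tm <- seq(-167, 667, length.out = 215)
  a <- matrix(rnorm(12 * 215), 12)
  b <- matrix(rnorm(12 * 215), 12)
  bump <- exp(-((tm - 300) / 60)^2)
  a <- a + matrix(2 * bump, 12, 215, byrow = TRUE)
  r1 <- cluster_test_paired(a, b, tm, n_perm = 1000, seed = 3)
  r2 <- cluster_test_paired(b, a, tm, n_perm = 1000, seed = 3)
  expect_equal(r1$clusters$mass, -r2$clusters$mass)
  expect_equal(r1$clusters$p, r2$clusters$p)
  # scaling leaves t untouched; borderline suprathreshold points may flip by
  # float rounding, so compare p within Monte-Carlo resolution
  r3 <- cluster_test_paired(10 * a, 10 * b, tm, n_perm = 1000, seed = 3)
  expect_equal(r1$clusters$p, r3$clusters$p, tolerance = 0.02)
  expect_true(any(r1$clusters$significant))
})

test_that("injected differences are detected where they were injected", {
  tm <- seq(-167, 667, length.out = 215)
  bump <- ifelse(tm >= 200 & tm <= 400,
                 sin(pi * (tm - 200) / 200), 0)
  hits <- 0
  n_runs <- 20
  for (r in seq_len(n_runs)) {
    set.seed(100 + r)
    a <- matrix(rnorm(14 * 215), 14) + matrix(1.5 * bump, 14, 215,
                                              byrow = TRUE)
    b <- matrix(rnorm(14 * 215), 14)
    res <- cluster_test_paired(a, b, tm, n_perm = 500, seed = r)
    sig <- res$clusters[res$clusters$significant, ]
    if (nrow(sig) && any(sig$start_ms <= 400 & sig$end_ms >= 200))
      hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("permutation p-values stabilize at 10,000 permutations", {
  set.seed(9)
  tm <- seq(0, 667, length.out = 172)
  x <- matrix(rnorm(14 * 172), 14) +
    matrix(0.75 * exp(-((tm - 300) / 80)^2), 14, 172, byrow = TRUE)
  r1 <- cluster_test_vs_zero(x, tm, n_perm = 10000, seed = 1)$clusters
  r2 <- cluster_test_vs_zero(x, tm, n_perm = 10000, seed = 2)$clusters
  expect_equal(nrow(r1), nrow(r2))
  # the decision-relevant cluster (largest |mass|) has a stable p-value
  i <- which.max(abs(r1$mass))
  expect_lt(abs(r1$p[i] - r2$p[i]), 0.01)
})
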
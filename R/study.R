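#' Full study configuration
#'
#' Bundles the generator settings and every analysis parameter of
#' [run_study()]. Defaults encode the standard paradigm: 0.05-100 Hz
#' band-pass, 50/100/150 Hz notches, 256 Hz resampling, -2..76 s segments,
#' 83-cycle crops from 2 s, 24+24 neighbor bins skipping the adjacent bin,
#' z thresholds 2.3 (harmonic selection) and 1.64 (individual
#' significance), 0-667 ms cluster window with 10,000 permutations at
#' point alpha 0.05.
#'
#' @param generator a [generator_config()].
#' @param nb a [neighbor_spec()].
#' @param bandpass band-pass edges, Hz.
#' @param line,notch line frequency and whether to notch it.
#' @param resample analysis rate, Hz.
#' @param seg_pre,seg_post segmentation window, s.
#' @param crop_start,n_cycles integer-cycle crop parameters.
#' @param z_select harmonic-selection threshold.
#' @param z_individual individual-significance threshold.
#' @param f_max_oddball,f_max_base harmonic-walk caps, Hz.
#' @param cluster_window,n_perm,point_alpha cluster-test parameters.
#' @param rois ROI layout, see [roi_layout()].
#' @param seed master seed (defaults to the generator's).
#' @return An object of class `fpvs_study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         nb = neighbor_spec(),
                         bandpass = c(0.05, 100), line = 50, notch = TRUE,
                         resample = 256, seg_pre = 2, seg_post = 76,
                         crop_start = 2, n_cycles = 83,
                         z_select = 2.3, z_individual = 1.64,
                         f_max_oddball = 40, f_max_base = 80,
                         cluster_window = c(0, 667), n_perm = 10000,
                         point_alpha = 0.05, rois = roi_layout(),
                         seed = NULL) {
  cfg <- list(generator = generator, nb = nb, bandpass = bandpass,
              line = line, notch = notch, resample = resample,
              seg_pre = seg_pre, seg_post = seg_post,
              crop_start = crop_start, n_cycles = n_cycles,
              z_select = z_select, z_individual = z_individual,
              f_max_oddball = f_max_oddball, f_max_base = f_max_base,
              cluster_window = cluster_window, n_perm = n_perm,
              point_alpha = point_alpha, rois = rois,
              seed = as.integer(seed %||% generator$seed))
  if (abs(generator$base_freq / generator$oddball_freq -
          round(generator$base_freq / generator$oddball_freq)) > 1e-9)
    stopf("base_freq must be an integer multiple of oddball_freq")
  class(cfg) <- "fpvs_study_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run a complete synthetic-study analysis
#'
#' Streams the synthetic recordings of [study_index()] one at a time through
#' preprocessing, frequency-domain quantification and time-domain averaging,
#' then computes harmonic sets from the grand-averaged spectrum,
#' per-participant summed-harmonic amplitudes/SNR/z-scores per channel and
#' ROI, group condition ratios, and ROI cluster-permutation tests. Fully
#' deterministic given the config seed.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional output directory; if given, result tables are
#'   written as TSV plus a JSON run log (removed again if any stage fails).
#' @param verbose print progress to stderr.
#' @return list with `metrics` (per participant x condition x ROI),
#'   `channel_metrics` (per channel), `ratios`, `harmonics` (oddball and
#'   base [harmonic_set()]s), `waveforms` (ROI-mean epoch averages, long
#'   data.frame), `clusters` (list of `fpvs_cluster_test`s), `grand_spectrum`
#'   and `log` (seeds and parameters).
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "fpvs_study_config"))
  gen <- cfg$generator
  idx <- study_index(gen)
  topo <- topography_weights(gen$channel_labels)
  rate_out <- cfg$resample %||% gen$rate
  combos <- unique(idx[, c("participant", "participant_id", "condition")])
  spec_sum <- list(); spec_n <- list()
  wave_sum <- list(); wave_n <- list()
  time_ms <- NULL
  freqs <- NULL
  for (i in seq_len(nrow(idx))) {
    row <- idx[i, ]
    key <- paste(row$participant_id, row$condition, sep = ".")
    rec <- stage("simulate", generate_sequence(
      gen, topo, row$condition, seed = row$seed, gain = row$gain,
      participant_id = row$participant_id))
    segs <- stage("preprocess", preprocess_recording(
      rec, low = cfg$bandpass[1], high = cfg$bandpass[2], line = cfg$line,
      notch = cfg$notch, resample = cfg$resample, pre = cfg$seg_pre,
      post = cfg$seg_post))
    seg <- segs[[1]]
    ep <- stage("crop", crop_integer_cycles(
      seg, oddball_freq = gen$oddball_freq, start = cfg$crop_start,
      n_cycles = cfg$n_cycles))
    spec <- stage("spectrum", amplitude_spectrum(ep))
    if (is.null(spec_sum[[key]])) {
      spec_sum[[key]] <- spec$amplitude
      spec_n[[key]] <- 1L
    } else {
      spec_sum[[key]] <- spec_sum[[key]] + spec$amplitude
      spec_n[[key]] <- spec_n[[key]] + 1L
    }
    freqs <- spec$freqs; resolution <- spec$resolution
    epw <- stage("timedomain", {
      tw <- prepare_waveforms(seg, oddball_freq = gen$oddball_freq,
                              start = cfg$crop_start, n_cycles = cfg$n_cycles)
      tw <- remove_base_harmonics(tw, base = gen$base_freq)
      epoch_and_average(tw, oddball_freq = gen$oddball_freq,
                        base_freq = gen$base_freq,
                        crop_start_s = cfg$crop_start)
    })
    if (is.null(wave_sum[[key]])) {
      wave_sum[[key]] <- epw$waveform
      wave_n[[key]] <- 1L
    } else {
      wave_sum[[key]] <- wave_sum[[key]] + epw$waveform
      wave_n[[key]] <- wave_n[[key]] + 1L
    }
    time_ms <- epw$time_ms
    if (verbose) message(sprintf("processed %s %s sequence %d",
                                 row$participant_id, row$condition,
                                 row$sequence))
  }
  mk_spec <- function(amp) {
    structure(list(amplitude = amp, freqs = freqs, resolution = resolution,
                   kind = "raw", channel_labels = gen$channel_labels),
              class = "fpvs_spectrum")
  }
  part_specs <- lapply(names(spec_sum),
                       function(k) mk_spec(spec_sum[[k]] / spec_n[[k]]))
  names(part_specs) <- names(spec_sum)
  grand <- mk_spec(Reduce(`+`, lapply(part_specs, `[[`, "amplitude")) /
                     length(part_specs))
  hs_odd <- stage("harmonics", select_harmonics(
    grand, gen$oddball_freq, exclude_multiples_of = gen$base_freq,
    z_threshold = cfg$z_select, f_max = cfg$f_max_oddball, nb = cfg$nb))
  hs_base <- stage("harmonics", select_harmonics(
    grand, gen$base_freq, z_threshold = cfg$z_select,
    f_max = cfg$f_max_base, nb = cfg$nb))
  if (!length(hs_odd$harmonics)) stopf("stage 'harmonics' failed: no significant oddball harmonic")
  roi_sets <- c(cfg$rois, list(all_channels = gen$channel_labels))
  chan_rows <- list(); roi_rows <- list()
  for (k in names(part_specs)) {
    ps <- part_specs[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    sbl <- baseline_subtract(ps, cfg$nb)
    snr <- snr_spectrum(ps, cfg$nb)
    sum_sbl <- summed_response(sbl, hs_odd)
    sum_snr <- summed_response(snr, hs_odd)
    sum_base <- summed_response(sbl, hs_base)
    chan_rows[[k]] <- data.frame(
      participant = parts[1], condition = parts[2],
      channel = names(sum_sbl), oddball_sbl_uv = unname(sum_sbl),
      oddball_snr_sum = unname(sum_snr), base_sbl_uv = unname(sum_base))
    zs <- lapply(roi_sets, function(chs)
      summed_zscore(ps, hs_odd, cfg$nb, channels = chs,
                    threshold = cfg$z_individual))
    roi_rows[[k]] <- data.frame(
      participant = parts[1], condition = parts[2], roi = names(roi_sets),
      oddball_sbl_uv = vapply(names(roi_sets), function(r)
        mean(sum_sbl[roi_sets[[r]]]), 1.0),
      base_sbl_uv = vapply(names(roi_sets), function(r)
        mean(sum_base[roi_sets[[r]]]), 1.0),
      z = vapply(zs, `[[`, 1.0, "z"),
      significant = vapply(zs, `[[`, TRUE, "significant"))
  }
  channel_metrics <- do.call(rbind, unname(chan_rows))
  metrics <- do.call(rbind, unname(roi_rows))
  rownames(metrics) <- NULL
  ratios <- do.call(rbind, lapply(c("OT", "all_channels"), function(scope) {
    m <- metrics[metrics$roi == scope, ]
    fam <- mean(m$oddball_sbl_uv[m$condition == "familiar"])
    unf <- mean(m$oddball_sbl_uv[m$condition == "unfamiliar"])
    data.frame(scope = scope, familiar_mean_uv = fam, unfamiliar_mean_uv = unf,
               ratio = fam / unf, unfamiliar_pct = 100 * unf / fam)
  }))
  # time-domain: ROI-mean waveform matrices per condition
  wave_rois <- cfg$rois[c("OT_left", "OT_right", "OT")]
  pids <- unique(idx$participant_id)
  wmats <- list()
  for (r in names(wave_rois)) {
    for (cond in c("familiar", "unfamiliar")) {
      wmats[[paste(r, cond, sep = ".")]] <- t(vapply(pids, function(p) {
        w <- wave_sum[[paste(p, cond, sep = ".")]] /
          wave_n[[paste(p, cond, sep = ".")]]
        colMeans(w[wave_rois[[r]], , drop = FALSE])
      }, numeric(length(time_ms))))
    }
  }
  clusters <- list()
  for (r in names(wave_rois)) {
    clusters[[paste0(r, ".familiar_vs_unfamiliar")]] <- stage("cluster",
      cluster_test_paired(wmats[[paste(r, "familiar", sep = ".")]],
                          wmats[[paste(r, "unfamiliar", sep = ".")]],
                          time_ms, window = cfg$cluster_window,
                          n_perm = cfg$n_perm, point_alpha = cfg$point_alpha,
                          seed = derive_seed(cfg$seed, 901, match(r, names(wave_rois)))))
    for (cond in c("familiar", "unfamiliar")) {
      clusters[[paste0(r, ".", cond, "_vs_zero")]] <- stage("cluster",
        cluster_test_vs_zero(wmats[[paste(r, cond, sep = ".")]], time_ms,
                             window = cfg$cluster_window, n_perm = cfg$n_perm,
                             point_alpha = cfg$point_alpha,
                             seed = derive_seed(cfg$seed, 902,
                                                match(r, names(wave_rois)),
                                                match(cond, c("familiar", "unfamiliar")))))
    }
  }
  waveforms <- do.call(rbind, lapply(names(wmats), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(roi = parts[1], condition = parts[2],
               time_ms = rep(time_ms, each = length(pids)),
               participant = rep(pids, times = length(time_ms)),
               amplitude_uv = as.vector(wmats[[k]]))
  }))
  log <- list(seed = cfg$seed, n_recordings = nrow(idx),
              recording_seeds = idx[, c("participant_id", "condition",
                                        "sequence", "seed")],
              generator = gen[setdiff(names(gen), "channel_labels")],
              analysis = cfg[c("bandpass", "line", "notch", "resample",
                               "crop_start", "n_cycles", "z_select",
                               "z_individual", "n_perm", "point_alpha")],
              oddball_harmonics = hs_odd$harmonics,
              base_harmonics = hs_base$harmonics)
  res <- list(metrics = metrics, channel_metrics = channel_metrics,
              ratios = ratios,
              harmonics = list(oddball = hs_odd, base = hs_base),
              waveforms = waveforms, clusters = clusters,
              grand_spectrum = grand, time_ms = time_ms, log = log)
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) { unlink(written); stop(e) }
  tryCatch({
    wt <- function(df, name) {
      path <- file.path(out_dir, name)
      write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, path)
    }
    wt(res$metrics, "metrics.tsv")
    wt(res$channel_metrics, "channel_metrics.tsv")
    wt(res$ratios, "ratios.tsv")
    wt(res$waveforms, "waveforms.tsv")
    cl <- do.call(rbind, lapply(names(res$clusters), function(k) {
      tab <- res$clusters[[k]]$clusters
      if (!nrow(tab)) return(NULL)
      cbind(contrast = k, tab[, c("start_ms", "end_ms", "mass", "p",
                                  "significant")])
    }))
    if (is.null(cl))
      cl <- data.frame(contrast = character(0), start_ms = numeric(0),
                       end_ms = numeric(0), mass = numeric(0),
                       p = numeric(0), significant = logical(0))
    wt(cl, "clusters.tsv")
    path <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(res$log, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
  }, error = on_fail)
  invisible(out_dir)
}
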
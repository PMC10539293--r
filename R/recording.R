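#' Multi-channel EEG recording container
#'
#' A lightweight container for a continuous multi-channel EEG trace: a
#' channels x time matrix of microvolt samples, a sample rate, ordered channel
#' labels, an event table (time in seconds, integer code) and free-form
#' metadata (condition label, participant id).
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sample rate in Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#' @param events data.frame with columns `time` (s) and `code` (integer), or
#'   NULL for none.
#' @param condition optional condition label.
#' @param participant_id optional participant label.
#' @return An object of class `fpvs_recording`.
#' @export
recording <- function(samples, rate, channel_labels,
                      events = NULL, condition = NA_character_,
                      participant_id = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels))
    stopf("channel_labels length (%d) does not match sample rows (%d)",
          length(channel_labels), nrow(samples))
  if (!is.numeric(rate) || rate <= 0) stopf("rate must be positive")
  if (is.null(events)) events <- data.frame(time = numeric(0), code = integer(0))
  dur <- ncol(samples) / rate
  if (nrow(events) && any(events$time < 0 | events$time > dur))
    stopf("event times outside record duration [0, %.3f s]", dur)
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, rate = rate, channel_labels = channel_labels,
         events = events, condition = condition,
         participant_id = participant_id),
    class = "fpvs_recording"
  )
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf(
    "<fpvs_recording> %d channels x %.2f s @ %g Hz, %d event(s)%s%s\n",
    nrow(x$samples), ncol(x$samples) / x$rate, x$rate, nrow(x$events),
    if (!is.na(x$condition)) paste0(", condition=", x$condition) else "",
    if (!is.na(x$participant_id)) paste0(", ", x$participant_id) else ""))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$rate

#' Read an EEG recording from disk
#'
#' Supports the package's internal container (R serialization, bit-exact
#' round trip), 16-bit EDF and 24-bit BioSemi BDF. For EDF/BDF, samples are
#' converted to physical units (microvolts) using the per-channel scaling in
#' the header, and events are taken from a BioSemi-style `Status` channel
#' (onsets of nonzero code runs).
#'
#' @param path file path.
#' @param format one of "auto", "internal", "edf", "bdf". "auto" picks by
#'   extension (.rds internal, .edf, .bdf).
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "internal", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     rds = "internal", edf = "edf", bdf = "bdf",
                     stopf("cannot infer format from extension of %s", path))
  }
  if (format == "internal") {
    rec <- readRDS(path)
    if (!inherits(rec, "fpvs_recording"))
      stopf("%s does not hold an fpvs_recording", path)
    return(rec)
  }
  read_edf_like(path, bits = if (format == "bdf") 24L else 16L)
}

#' Write an EEG recording to disk
#'
#' @param rec an [recording()] object.
#' @param path destination file path.
#' @param format "internal" (R serialization) or "edf" (16-bit EDF with a
#'   `Status` event channel).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("internal", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "fpvs_recording"))
  if (format == "internal") saveRDS(rec, path) else write_edf(rec, path)
  invisible(path)
}

# ---- EDF / BDF ----

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples) + 1L          # + Status channel
  rate <- rec$rate
  if (rate != round(rate)) stopf("EDF export requires an integer sample rate")
  n_rec <- ceiling(ncol(rec$samples) / rate)   # 1 s data records
  npad <- n_rec * rate - ncol(rec$samples)
  x <- cbind(rec$samples, matrix(0, nrow(rec$samples), npad))
  status <- integer(ncol(x))
  if (nrow(rec$events)) {
    idx <- pmin(ncol(x), round(rec$events$time * rate) + 1L)
    status[idx] <- as.integer(rec$events$code)
  }
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  labels <- c(rec$channel_labels, "Status")
  for (f in labels) writeChar(pad_field(f, 16), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field("Active electrode", 80), con, eos = NULL)
  dims <- c(rep("uV", ns - 1), "")
  for (f in dims) writeChar(pad_field(f, 8), con, eos = NULL)
  phys_min <- c(pmin_, dmin); phys_max <- c(pmax_, dmax)
  for (f in formatC(phys_min, digits = 6, format = "g"))
    writeChar(pad_field(f, 8), con, eos = NULL)
  for (f in formatC(phys_max, digits = 6, format = "g"))
    writeChar(pad_field(f, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field(dmin, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field(dmax, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field("", 80), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field(rate, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(pad_field("", 32), con, eos = NULL)
  # digital encoding
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns - 1)) {
      dig <- as.integer(round((x[ch, sl] - pmin_[ch]) * gain[ch] + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
    writeBin(status[sl], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_like <- function(path, bits = 16L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < n)
      stopf("truncated header in %s", path)
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("unparseable channel count in %s", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  samp_bytes <- bits / 8
  expect <- sum(nsamp) * samp_bytes * n_rec
  avail <- file.size(path) - (256 + ns * 256)
  if (avail < expect)
    stopf("truncated data in %s: expected %d bytes, found %d", path, expect, avail)
  raw_all <- readBin(con, "raw", n = expect)
  is_status <- grepl("^Status", labels)
  rate <- nsamp[1] / rec_dur
  data <- matrix(0, ns, n_rec * nsamp[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      nb <- nsamp[ch] * samp_bytes
      chunk <- raw_all[(pos + 1):(pos + nb)]
      pos <- pos + nb
      if (bits == 16L) {
        v <- readBin(chunk, "integer", n = nsamp[ch], size = 2,
                     endian = "little", signed = TRUE)
      } else {
        b <- as.integer(chunk)
        i1 <- b[seq(1, nb, 3)]; i2 <- b[seq(2, nb, 3)]; i3 <- b[seq(3, nb, 3)]
        v <- i1 + 256 * i2 + 65536 * i3
        v <- ifelse(v >= 8388608, v - 16777216, v)
      }
      sl <- ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])
      data[ch, sl] <- v
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (ch in which(!is_status))
    data[ch, ] <- (data[ch, ] - dig_min[ch]) * gain[ch] + phys_min[ch]
  events <- data.frame(time = numeric(0), code = integer(0))
  if (any(is_status)) {
    st <- as.integer(data[which(is_status)[1], ])
    st_mask <- bitwAnd(st, 65535L)     # BioSemi packs triggers in low bytes
    on <- which(st_mask != 0 & c(0L, head(st_mask, -1)) == 0L)
    if (length(on))
      events <- data.frame(time = (on - 1) / rate, code = st_mask[on])
  }
  keep <- !is_status
  recording(data[keep, , drop = FALSE], rate, labels[keep], events)
}
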
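#' Stimulus image record
#'
#' Grayscale image with optional landmarks and face mask, as used by the
#' image-set statistics. Pixel origin is top-left, x rightward, y downward.
#'
#' @param pixels numeric matrix (height x width), intensities in [0, 1] (8-bit
#'   input is rescaled).
#' @param landmarks optional list with numeric (x, y) entries `nose`,
#'   `left_pupil`, `right_pupil`.
#' @param mask optional logical matrix of the same shape marking face pixels.
#' @return An object of class `fpvs_image`.
#' @export
image_record <- function(pixels, landmarks = NULL, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (!length(pixels)) stopf("empty image")
  if (max(pixels, na.rm = TRUE) > 1) pixels <- pixels / 255
  if (!is.null(mask)) {
    mask <- as.matrix(mask) > 0
    if (!all(dim(mask) == dim(pixels)))
      stopf("mask shape %s does not match image %s",
            paste(dim(mask), collapse = "x"), paste(dim(pixels), collapse = "x"))
  }
  if (!is.null(landmarks)) {
    for (nm in names(landmarks)) {
      p <- landmarks[[nm]]
      if (p[1] < 1 || p[1] > ncol(pixels) || p[2] < 1 || p[2] > nrow(pixels))
        stopf("landmark '%s' outside image bounds", nm)
    }
  }
  structure(list(pixels = pixels, landmarks = landmarks, mask = mask),
            class = "fpvs_image")
}

#' Read an image (with optional landmarks and mask) from disk
#'
#' PNG images are converted to grayscale with luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B) when they have color channels.
#'
#' @param path PNG file path.
#' @param landmarks optional named list as in [image_record()].
#' @param mask_path optional PNG mask path (nonzero = face).
#' @return An `fpvs_image`.
#' @export
read_image <- function(path, landmarks = NULL, mask_path = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    w <- c(0.2126, 0.7152, 0.0722)[seq_len(min(3, dim(px)[3]))]
    w <- w / sum(w)
    px <- Reduce(`+`, lapply(seq_along(w), function(i) w[i] * px[, , i]))
  }
  mask <- if (!is.null(mask_path)) png::readPNG(mask_path) > 0 else NULL
  if (!is.null(mask) && length(dim(mask)) == 3) mask <- mask[, , 1]
  image_record(px, landmarks = landmarks, mask = mask)
}

#' Mean luminance and RMS contrast
#'
#' @param img an [image_record()].
#' @return named numeric vector `c(luminance, contrast)`: mean pixel
#'   intensity and the SD of pixel intensities (RMS contrast).
#' @export
luminance_and_contrast <- function(img) {
  px <- img$pixels
  n <- length(px)
  m <- mean(px)
  c(luminance = m, contrast = sqrt(sum((px - m)^2) / n))
}

#' Head-orientation ratio
#'
#' Ratio of the Euclidean distance from nose tip to left pupil over the
#' distance from nose tip to right pupil. Values near 1 indicate a frontal
#' view; values below 1 indicate a leftward-oriented face.
#'
#' @param img an [image_record()] with all three landmarks.
#' @return numeric ratio.
#' @export
orientation_ratio <- function(img) {
  lm <- img$landmarks
  if (is.null(lm) || is.null(lm$nose) || is.null(lm$left_pupil) ||
      is.null(lm$right_pupil))
    stopf("orientation ratio needs nose and both pupil landmarks")
  d <- function(a, b) sqrt(sum((a - b)^2))
  dr <- d(lm$nose, lm$right_pupil)
  if (dr == 0) stopf("nose and right pupil coincide: ratio undefined")
  d(lm$nose, lm$left_pupil) / dr
}

#' Face-area fraction
#'
#' Percentage of image pixels covered by the face mask.
#'
#' @param img an [image_record()] with a mask.
#' @return numeric percentage in (0, 100].
#' @export
face_area_fraction <- function(img) {
  if (is.null(img$mask)) stopf("face area needs a mask")
  if (!any(img$mask)) stopf("empty face mask")
  100 * sum(img$mask) / length(img$mask)
}

#' Radial amplitude profile of an image
#'
#' 2-D FFT amplitude spectrum, restricted to the central square matching the
#' smaller image dimension, averaged over integer radial-frequency annuli
#' 1 ... m/2 cycles/image (100 bins for a 200-pixel smaller dimension; DC
#' excluded).
#'
#' @param img an [image_record()].
#' @param crop side of the central square, pixels (default: the smaller
#'   dimension).
#' @return numeric vector of mean amplitudes, one per cycles/image annulus.
#' @export
radial_amplitude_profile <- function(img, crop = NULL) {
  px <- img$pixels
  m <- crop %||% min(dim(px))
  if (min(dim(px)) < m) stopf("image smaller than the requested crop")
  amp <- Mod(fft(px)) / length(px)
  # central m x m block of the centered spectrum
  kx <- c(0:floor(ncol(px) / 2), -(ceiling(ncol(px) / 2) - 1):-1)
  ky <- c(0:floor(nrow(px) / 2), -(ceiling(nrow(px) / 2) - 1):-1)
  keepx <- abs(kx) <= m / 2
  keepy <- abs(ky) <= m / 2
  amp <- amp[keepy, keepx, drop = FALSE]
  r <- sqrt(outer(ky[keepy]^2, kx[keepx]^2, "+"))
  ann <- round(r)
  nb <- floor(m / 2)
  vapply(seq_len(nb), function(k) mean(amp[ann == k]), 1.0)
}

#' Log-log slope of a radial amplitude profile
#'
#' Ordinary least-squares slope of log(amplitude) against log(frequency).
#' Non-positive amplitudes are excluded with a warning.
#'
#' @param profile radial amplitude profile (see
#'   [radial_amplitude_profile()]).
#' @param freqs frequencies for each profile value (default 1 ... length).
#' @return numeric slope.
#' @export
loglog_slope <- function(profile, freqs = seq_along(profile)) {
  ok <- profile > 0 & is.finite(profile)
  if (!all(ok)) warnf("excluding %d non-positive profile value(s) from fit",
                      sum(!ok))
  if (sum(ok) < 2) stopf("fewer than 2 positive profile values")
  unname(coef(lm(log(profile[ok]) ~ log(freqs[ok])))[2])
}

#' Two-set permutation test
#'
#' Difference-of-means (or medians) permutation test between two sets of
#' values: the null is built by randomly relabeling the pooled observations,
#' and the p-value is the add-one-corrected proportion of permuted
#' statistics at least as extreme as the observed one.
#'
#' @param a,b numeric vectors.
#' @param n_perm number of permutations.
#' @param tails 2 (two-tailed, on the absolute statistic) or 1 (one-tailed,
#'   a greater than b).
#' @param seed RNG seed.
#' @param statistic "mean" or "median".
#' @return list with `p`, `observed` statistic, `n_perm`.
#' @export
permutation_test_sets <- function(a, b, n_perm = 10000, tails = 2,
                                  seed = 1L, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!length(a) || !length(b)) stopf("both sets must be non-empty")
  if (n_perm < 100) warnf("n_perm = %d is very small", n_perm)
  st <- if (statistic == "mean") mean else median
  obs <- st(a) - st(b)
  pool <- c(a, b)
  na <- length(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    st(pool[idx]) - st(pool[-idx])
  }, 1.0))
  hits <- if (tails == 2) sum(abs(perm) >= abs(obs) - 1e-12)
          else sum(perm >= obs - 1e-12)
  list(p = (1 + hits) / (1 + n_perm), observed = obs, n_perm = n_perm)
}

#' Image-set statistics table
#'
#' Per-image luminance, RMS contrast, orientation ratio and face-area
#' fraction, plus the set-level radial amplitude profile (mean across
#' images) and its log-log slope.
#'
#' @param images list of [image_record()]s.
#' @return list with `per_image` (data.frame) and `profile`, `slope`.
#' @export
image_set_stats <- function(images) {
  per <- do.call(rbind, lapply(seq_along(images), function(i) {
    img <- images[[i]]
    lc <- luminance_and_contrast(img)
    data.frame(
      image = i, luminance = lc[["luminance"]], contrast = lc[["contrast"]],
      orientation_ratio = if (!is.null(img$landmarks))
        orientation_ratio(img) else NA_real_,
      face_area_pct = if (!is.null(img$mask))
        face_area_fraction(img) else NA_real_)
  }))
  profiles <- vapply(images, radial_amplitude_profile,
                     radial_amplitude_profile(images[[1]]))
  profile <- rowMeans(profiles)
  list(per_image = per, profile = profile, slope = loglog_slope(profile))
}
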
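## Spectral preprocessing chain.
##
## Quantification mode:  crop -> background removal -> rubber-band -> average
## Classification mode:  crop -> background removal -> SG 2nd deriv -> SNV
##                       -> average
## All per-spectrum operations act row-wise on matrices so whole images and
## cohorts are processed without copying into per-spectrum objects.

#' Preprocessing configuration
#'
#' @param crop_high,crop_low Fingerprint-region crop bounds in cm^-1
#'   (defaults 1801 and 798).
#' @param sg_window Savitzky-Golay window length in points (odd, default 9).
#' @param sg_polyorder Fitting polynomial order (default 3).
#' @param sg_deriv Derivative order (default 2).
#' @param background_band [band_definition()] whose integrated area decides
#'   tissue vs background (default amide I, the dominant tissue band).
#' @param background_fraction Pixels whose corrected band area falls below
#'   this fraction of the image maximum are background (default 0.10).
#' @param n_avg Number of representative spectra per sample after averaging
#'   (default 25).
#' @param avg_seed Seed for the averaging partition.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_high = 1801, crop_low = 798,
                              sg_window = 9, sg_polyorder = 3, sg_deriv = 2,
                              background_band = band_definition("amide_I", 1700, 1600),
                              background_fraction = 0.10,
                              n_avg = 25, avg_seed = 0L) {
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder)
    stop_config("sg_window must be odd and > sg_polyorder")
  if (sg_polyorder < sg_deriv) stop_config("sg_polyorder must be >= sg_deriv")
  if (crop_high <= crop_low) stop_config("crop_high must exceed crop_low")
  if (background_fraction <= 0 || background_fraction >= 1)
    stop_config("background_fraction must be in (0, 1)")
  if (n_avg < 1) stop_config("n_avg must be >= 1")
  structure(list(crop_high = crop_high, crop_low = crop_low,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 background_band = background_band,
                 background_fraction = background_fraction,
                 n_avg = as.integer(n_avg), avg_seed = as.integer(avg_seed)),
            class = "preprocess_config")
}

## Crop ---------------------------------------------------------------------

# Axis indices retained by a closed [low, high] crop.
crop_index <- function(axis, high, low) {
  if (high <= low) stop_config("crop bounds must satisfy high > low")
  v <- axis_values(axis)
  idx <- which(v >= low & v <= high)
  if (length(idx) < 2L)
    stop_range("crop window %g-%g cm^-1 retains fewer than 2 axis points",
               high, low)
  idx
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains exactly the axis points inside the closed window `[low, high]`,
#' preserving the descending order.
#'
#' @param x An [ftir_spectrum()] or [spectra_set()].
#' @param high,low Window bounds in cm^-1.
#' @return Object of the same class on the cropped axis.
#' @export
crop_spectrum <- function(x, high, low) UseMethod("crop_spectrum")

#' @export
crop_spectrum.ftir_spectrum <- function(x, high, low) {
  idx <- crop_index(x$axis, high, low)
  ftir_spectrum(wn_axis(axis_values(x$axis)[idx]), x$absorbance[idx], x$meta)
}

#' @export
crop_spectrum.spectra_set <- function(x, high, low) {
  idx <- crop_index(x$axis, high, low)
  spectra_set(wn_axis(axis_values(x$axis)[idx]), x$X[, idx, drop = FALSE], x$meta)
}

## Rubber-band baseline -----------------------------------------------------

# Lower convex hull (Andrew monotone chain) of (x, y) with x ascending;
# returns the baseline evaluated at every x by linear interpolation between
# hull vertices.
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    while (h >= 2L) {
      a <- hull[h - 1L]; b <- hull[h]
      # pop b if it lies on/above the chord a--i (cross product <= 0)
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        h <- h - 1L
      else break
    }
    h <- h + 1L
    hull[h] <- i
  }
  hull <- hull[seq_len(h)]
  stats::approx(x[hull], y[hull], xout = x, method = "linear")$y
}

# Matrix version: row-wise baselines for spectra stored on a descending axis.
.rubberband_matrix <- function(X, axis) {
  v <- axis_values(axis)
  if (length(v) < 3L) stop_shape("rubber-band correction needs >= 3 points")
  asc <- rev(seq_along(v))            # ascending-x view of the descending axis
  xs <- v[asc]
  B <- t(apply(X, 1L, function(y) lower_hull_baseline(xs, y[asc])[order(asc)]))
  if (nrow(X) == 1L) B <- matrix(B, 1L)
  B
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex hull of the points `(wavenumber, absorbance)`,
#' evaluated by linear interpolation between hull vertices. The corrected
#' spectrum is non-negative and exactly zero at every hull vertex, including
#' both endpoints.
#'
#' @param x An [ftir_spectrum()] or [spectra_set()].
#' @return For a spectrum: list with `corrected` and `baseline` spectra. For
#'   a set: list with `corrected` and `baseline` sets.
#' @export
rubberband_baseline <- function(x) UseMethod("rubberband_baseline")

#' @export
rubberband_baseline.ftir_spectrum <- function(x) {
  B <- .rubberband_matrix(matrix(x$absorbance, 1L), x$axis)
  list(corrected = ftir_spectrum(x$axis, pmax(x$absorbance - B[1, ], 0), x$meta),
       baseline = ftir_spectrum(x$axis, B[1, ], x$meta))
}

#' @export
rubberband_baseline.spectra_set <- function(x) {
  B <- .rubberband_matrix(x$X, x$axis)
  list(corrected = spectra_set(x$axis, pmax(x$X - B, 0), x$meta),
       baseline = spectra_set(x$axis, B, x$meta))
}

## Savitzky-Golay -----------------------------------------------------------

# Least-squares filter matrix (window x window) scaled so the output is the
# deriv-th derivative with respect to wavenumber; row i gives the filter for
# the i-th point of a window (interior points use the central row, edges use
# the off-centre rows, the standard SG edge treatment that stays exact for
# polynomials up to the fitting order). `step` is the signed axis step along
# storage order.
sg_filter_matrix <- function(window, polyorder, deriv, step) {
  Fm <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv,
                               ts = abs(step)))
  if (deriv %% 2 == 1 && step < 0) Fm <- -Fm
  Fm
}

# Row-wise filtering, preserving vector length.
.savgol_matrix <- function(X, axis, window, polyorder, deriv) {
  if (!is_uniform_axis(axis_values(axis)))
    stop_axis("Savitzky-Golay requires a uniform axis")
  if (window %% 2 != 1) stop_config("sg window must be odd")
  if (polyorder >= window) stop_config("sg window must exceed polyorder")
  if (deriv > polyorder) stop_config("sg deriv must be <= polyorder")
  k <- ncol(X)
  if (k < window) stop_shape("spectrum shorter than the SG window")
  half <- (window - 1L) %/% 2L
  Fm <- sg_filter_matrix(window, polyorder, deriv, axis_step(axis))
  coef <- Fm[half + 1L, ]
  out <- matrix(0, nrow(X), k)
  for (j in seq_len(window))
    out[, (half + 1L):(k - half)] <- out[, (half + 1L):(k - half)] +
      coef[j] * X[, j:(j + k - window), drop = FALSE]
  # leading/trailing edges: off-centre filter rows on the first/last window
  out[, seq_len(half)] <-
    X[, seq_len(window), drop = FALSE] %*% t(Fm[seq_len(half), , drop = FALSE])
  out[, (k - half + 1L):k] <-
    X[, (k - window + 1L):k, drop = FALSE] %*%
      t(Fm[(half + 2L):window, , drop = FALSE])
  out
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Convolution with least-squares polynomial filter coefficients; the
#' derivative is scaled by the signed axis step to the power `-deriv`, so a
#' second derivative is d2A/dv2 in absorbance * cm^2 regardless of point
#' spacing. Edges use the off-centre least-squares fits over the first/last
#' window (exact for polynomials up to the fitting order), so the output
#' length equals the input length.
#'
#' @param x An [ftir_spectrum()] or [spectra_set()].
#' @param window Odd filter length in points.
#' @param polyorder Polynomial order (> deriv).
#' @param deriv Derivative order (0 = smoothing).
#' @return Object of the same class as `x`.
#' @export
savitzky_golay <- function(x, window = 9, polyorder = 3, deriv = 2)
  UseMethod("savitzky_golay")

#' @export
savitzky_golay.ftir_spectrum <- function(x, window = 9, polyorder = 3, deriv = 2) {
  Y <- .savgol_matrix(matrix(x$absorbance, 1L), x$axis, window, polyorder, deriv)
  ftir_spectrum(x$axis, Y[1, ], x$meta)
}

#' @export
savitzky_golay.spectra_set <- function(x, window = 9, polyorder = 3, deriv = 2) {
  spectra_set(x$axis, .savgol_matrix(x$X, x$axis, window, polyorder, deriv), x$meta)
}

## SNV ----------------------------------------------------------------------

.snv_matrix <- function(X) {
  mu <- rowMeans(X)
  sd <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  if (any(sd == 0))
    stop_degenerate("constant spectrum cannot be SNV-normalised")
  (X - mu) / sd
}

#' Standard normal variate normalisation
#'
#' Centers each spectrum to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator) over the whole spectral region. Removes
#' multiplicative scatter and offset differences between spectra; idempotent
#' and invariant to positive affine transforms of the input.
#'
#' @param x An [ftir_spectrum()] or [spectra_set()].
#' @return Object of the same class as `x`.
#' @export
snv <- function(x) UseMethod("snv")

#' @export
snv.ftir_spectrum <- function(x) {
  if (length(x$absorbance) < 2L) stop_shape("SNV needs >= 2 points")
  ftir_spectrum(x$axis, .snv_matrix(matrix(x$absorbance, 1L))[1, ], x$meta)
}

#' @export
snv.spectra_set <- function(x) spectra_set(x$axis, .snv_matrix(x$X), x$meta)

## Background removal -------------------------------------------------------

#' Flag background pixels of a hyperspectral image
#'
#' A pixel is background when its rubber-band-corrected amide-I integrated
#' area falls below `background_fraction` times the image maximum of that
#' area. Amide I is used because it is the dominant tissue band. Existing
#' labels are preserved for surviving pixels; flagged pixels become -1.
#'
#' @param image A [hyper_image()] (already cropped or not).
#' @param cfg A [preprocess_config()].
#' @return The image with updated `labels`.
#' @export
remove_background <- function(image, cfg = preprocess_config()) {
  X <- cube_to_matrix(image)
  corr <- X - .rubberband_matrix(X, image$axis)
  idx <- band_index(image$axis, cfg$background_band)
  v <- axis_values(image$axis)[idx]
  areas <- apply(corr[, idx, drop = FALSE], 1L, function(y) trapz_abs(v, y))
  thr <- cfg$background_fraction * max(areas)
  keep <- areas >= thr & max(areas) > 0
  if (!any(keep)) stop_emptytissue("background removal discarded every pixel")
  d <- dim(image$cube)
  labels <- image$labels
  if (is.null(labels)) labels <- matrix(0L, d[1], d[2])
  labels[!matrix(keep, d[1], d[2])] <- -1L
  hyper_image(image$axis, image$cube, image$pixel_size_um, labels)
}

## Averaging ----------------------------------------------------------------

#' Average pixel spectra into representative spectra
#'
#' Shuffles the spectra with the given seed, partitions them into `n_avg`
#' near-equal bins (sizes differ by at most 1) and replaces each bin by its
#' pointwise mean. With fewer spectra than `n_avg`, every spectrum is its own
#' representative.
#'
#' @param x A [spectra_set()] of pixel spectra.
#' @param n_avg Number of representatives.
#' @param seed Shuffle seed.
#' @return A [spectra_set()] of `min(n_avg, n)` representatives.
#' @export
average_to_representatives <- function(x, n_avg = 25, seed = 0L) {
  n <- nrow(x$X)
  if (n == 0L) stop_shape("no spectra to average")
  if (n_avg < 1L) stop_config("n_avg must be >= 1")
  if (n <= n_avg) return(spectra_set(x$axis, x$X))
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_avg, n_avg) + c(rep(1L, n %% n_avg),
                                       rep(0L, n_avg - n %% n_avg))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_avg] + 1L)
  M <- t(vapply(seq_len(n_avg), function(b)
    colMeans(x$X[perm[starts[b]:ends[b]], , drop = FALSE]),
    numeric(ncol(x$X))))
  spectra_set(x$axis, M)
}

## Full pipeline ------------------------------------------------------------

#' Run the preprocessing chain on a hyperspectral image
#'
#' Quantification mode: crop, background removal, rubber-band baseline
#' correction, averaging. Classification mode: crop, background removal,
#' Savitzky-Golay second derivative, SNV, averaging. Both modes share the
#' same crop and background-removal stages, so they operate on identical
#' surviving pixel sets.
#'
#' @param image A [hyper_image()].
#' @param cfg A [preprocess_config()].
#' @param mode `"quantification"` or `"classification"`.
#' @return A [spectra_set()] of representative spectra on the cropped axis,
#'   with the stage sequence recorded in `attr(, "stages")`.
#' @export
preprocess_pipeline <- function(image, cfg = preprocess_config(),
                                mode = c("quantification", "classification")) {
  mode <- match.arg(mode)
  idx <- crop_index(image$axis, cfg$crop_high, cfg$crop_low)
  axis <- wn_axis(axis_values(image$axis)[idx])
  cropped <- hyper_image(axis, image$cube[, , idx, drop = FALSE],
                         image$pixel_size_um, image$labels)
  cleaned <- remove_background(cropped, cfg)
  keep <- as.vector(cleaned$labels) >= 0L
  pixels <- spectra_set(axis, cube_to_matrix(cleaned)[keep, , drop = FALSE])
  stages <- c("crop", "remove_background")
  if (mode == "quantification") {
    pixels <- rubberband_baseline(pixels)$corrected
    stages <- c(stages, "rubberband_baseline")
  } else {
    pixels <- savitzky_golay(pixels, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
    pixels <- snv(pixels)
    stages <- c(stages, "savitzky_golay", "snv")
  }
  out <- average_to_representatives(pixels, cfg$n_avg, cfg$avg_seed)
  stages <- c(stages, "average_to_representatives")
  if (mode == "classification") {
    # averaging mean-0/sd-1 spectra keeps mean 0 but shrinks the sd; a final
    # SNV pass (idempotent) keeps every representative exactly SNV-scaled
    out <- snv(out)
    stages <- c(stages, "snv")
  }
  attr(out, "stages") <- stages
  out
}

# Classification-mode chain for cohort records, whose spectra are already
# averaged representatives: crop -> SG -> SNV (quantification: crop ->
# rubber-band).
preprocess_record_spectra <- function(spectra, cfg, mode) {
  s <- crop_spectrum(spectra, cfg$crop_high, cfg$crop_low)
  if (mode == "classification")
    snv(savitzky_golay(s, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv))
  else
    rubberband_baseline(s)$corrected
}
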
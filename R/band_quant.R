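## Integrated-area biochemistry quantification and group comparisons.

#' Integrate a spectrum over a band window
#'
#' Trapezoidal integral over the wavenumber magnitude of the axis points
#' inside the closed window. Linear in the spectrum and non-negative for
#' non-negative input.
#'
#' @param spectrum An [ftir_spectrum()] (baseline-corrected for
#'   quantification use).
#' @param band A [band_definition()].
#' @return Integrated area in absorbance * cm^-1.
#' @export
integrate_band <- function(spectrum, band) {
  idx <- band_index(spectrum$axis, band)
  trapz_abs(axis_values(spectrum$axis)[idx], spectrum$absorbance[idx])
}

# Row-wise band areas for a spectra_set.
integrate_band_set <- function(set, band) {
  idx <- band_index(set$axis, band)
  v <- axis_values(set$axis)[idx]
  apply(set$X[, idx, drop = FALSE], 1L, function(y) trapz_abs(v, y))
}

#' Chemical map of a hyperspectral image
#'
#' Per-pixel integrated band area over rubber-band-corrected spectra;
#' background pixels (label -1) are set to `NA`.
#'
#' @param image A [hyper_image()], typically after [remove_background()].
#' @param band A [band_definition()].
#' @param baseline_correct Apply rubber-band correction per pixel before
#'   integrating (default TRUE).
#' @return Numeric matrix `rows x cols`; `NA` marks background.
#' @export
chemical_map <- function(image, band, baseline_correct = TRUE) {
  X <- cube_to_matrix(image)
  if (baseline_correct) X <- pmax(X - .rubberband_matrix(X, image$axis), 0)
  idx <- band_index(image$axis, band)
  v <- axis_values(image$axis)[idx]
  areas <- apply(X[, idx, drop = FALSE], 1L, function(y) trapz_abs(v, y))
  d <- dim(image$cube)
  m <- matrix(areas, d[1], d[2])
  if (!is.null(image$labels)) m[image$labels < 0L] <- NA_real_
  m
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with the Welch correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Object of class `welch_result`: `t_stat`, `df`, `p_value`,
#'   `mean_diff` (a - b), `group_ns`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_samplesize("Welch test needs >= 2 observations per group")
  if (anyNA(c(group_a, group_b)) || any(!is.finite(c(group_a, group_b))))
    stop_shape("Welch test requires finite values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      stop_degenerate("both groups constant and equal: t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_diff = mean(group_a) - mean(group_b),
                 group_ns = c(length(group_a), length(group_b))),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g, mean diff = %.4g (n = %d, %d)\n",
              x$t_stat, x$df, x$p_value, x$mean_diff, x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

# One area value per record: quantification preprocessing of the record's
# representatives, band integration, mean over representatives.
record_band_area <- function(record, band, cfg) {
  s <- preprocess_record_spectra(record$spectra, cfg, "quantification")
  mean(integrate_band_set(s, band))
}

#' Compare band areas between two severity classes
#'
#' Computes one integrated-area value per [sample_record()] (mean over its
#' representative spectra, after cropping and rubber-band correction) and
#' applies [welch_test()] across records. Records — imaged sections — are the
#' statistical unit, avoiding pixel-level pseudo-replication.
#'
#' @param cohort A [cohort_set()].
#' @param band A [band_definition()].
#' @param class_a,class_b Severity classes to compare (a - b in `mean_diff`).
#' @param layer Bowel layer to test within.
#' @param cfg A [preprocess_config()].
#' @param holm Apply no correction (default); retained as an option hook for
#'   callers testing several bands (`stats::p.adjust(..., "holm")` on the
#'   collected p-values).
#' @return A `welch_result`.
#' @export
compare_groups <- function(cohort, band, class_a, class_b, layer = "MC",
                           cfg = preprocess_config(), holm = FALSE) {
  recs_a <- cohort_subset(cohort, layer, class_a)
  recs_b <- cohort_subset(cohort, layer, class_b)
  if (length(recs_a) == 0L) stop_classabsent("no %s records in layer %s", class_a, layer)
  if (length(recs_b) == 0L) stop_classabsent("no %s records in layer %s", class_b, layer)
  a <- vapply(recs_a, record_band_area, 0, band = band, cfg = cfg)
  b <- vapply(recs_b, record_band_area, 0, band = band, cfg = cfg)
  welch_test(a, b)
}

#' Band-area table for a cohort
#'
#' @param cohort A [cohort_set()].
#' @param bands Named list of [band_definition()] (default
#'   [default_band_table()]).
#' @param cfg A [preprocess_config()].
#' @return data.frame: animal_id, section_id, layer, severity, band, area.
#' @export
quantify_cohort <- function(cohort, bands = default_band_table(),
                            cfg = preprocess_config()) {
  rows <- list()
  for (r in cohort$records) {
    s <- preprocess_record_spectra(r$spectra, cfg, "quantification")
    for (b in bands) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = r$animal_id, section_id = r$section_id, layer = r$layer,
        severity = r$severity, band = b$name,
        area = mean(integrate_band_set(s, b)))
    }
  }
  do.call(rbind, rows)
}
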
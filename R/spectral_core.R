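## Domain types: wavenumber axis, spectrum, hyperspectral image, cohort.
##
## Conventions: the wavenumber axis is stored descending (high -> low cm^-1),
## the FTIR convention under which band windows are quoted "1700-1600".
## Window arguments are always (high, low) and validated high > low; point
## selection inside a window is closed on both ends.

#' Construct a wavenumber axis
#'
#' Validates strict monotonicity and uniform spacing (required by the
#' Savitzky-Golay derivative filter), and canonicalizes to descending order.
#'
#' @param values Numeric vector of wavenumbers (cm^-1), strictly monotone in
#'   either direction.
#' @return An object of class `wn_axis`: the descending wavenumber vector with
#'   a `spacing` attribute (mean absolute step, cm^-1).
#' @export
wn_axis <- function(values) {
  values <- as.double(values)
  if (length(values) < 2L) stop_axis("axis needs at least 2 points")
  if (anyNA(values) || any(!is.finite(values))) stop_axis("axis values must be finite")
  d <- diff(values)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop_axis("axis must be strictly monotone")
  if (d[1] > 0) values <- rev(values)
  if (!is_uniform_axis(values))
    stop_axis("axis spacing must be uniform within 1e-6 relative tolerance")
  structure(values, spacing = mean(abs(diff(values))), class = "wn_axis")
}

#' Accessors for a wavenumber axis
#'
#' @param axis A [wn_axis()].
#' @return `axis_values()`: the descending numeric wavenumber vector;
#'   `axis_spacing()`: the point spacing in cm^-1.
#' @export
axis_values <- function(axis) as.double(unclass(axis))

#' @rdname axis_values
#' @export
axis_spacing <- function(axis) attr(axis, "spacing")

# Signed step along storage order (negative for the descending convention).
axis_step <- function(axis) mean(diff(axis_values(axis)))

#' @export
print.wn_axis <- function(x, ...) {
  v <- axis_values(x)
  cat(sprintf("<wn_axis> %d points, %.6g -> %.6g cm^-1, spacing %.6g cm^-1\n",
              length(v), v[1], v[length(v)], axis_spacing(x)))
  invisible(x)
}

#' Construct a single absorbance spectrum
#'
#' @param axis A [wn_axis()] (or numeric vector coerced through it).
#' @param absorbance Numeric vector of absorbance values (AU), same length as
#'   the axis, all finite.
#' @param meta Named list of metadata.
#' @return An object of class `ftir_spectrum` with fields `axis`, `absorbance`,
#'   `meta`.
#' @export
ftir_spectrum <- function(axis, absorbance, meta = list()) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  absorbance <- as.double(absorbance)
  if (length(absorbance) != length(axis_values(axis)))
    stop_shape("absorbance length (%d) != axis length (%d)",
               length(absorbance), length(axis_values(axis)))
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop_shape("absorbance values must be finite")
  structure(list(axis = axis, absorbance = absorbance, meta = meta),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  v <- axis_values(x$axis)
  cat(sprintf("<ftir_spectrum> %d points, %.6g -> %.6g cm^-1, A in [%.4g, %.4g]\n",
              length(v), v[1], v[length(v)],
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Canonicalize a raw (axis, values) pair into a spectrum
#'
#' Accepts an axis in either monotone direction, reorders to the descending
#' convention and reorders the values consistently. Idempotent: applying it to
#' an already canonical spectrum returns it unchanged.
#'
#' @param raw_axis Numeric wavenumbers, strictly monotone either way.
#' @param raw_values Absorbance values aligned with `raw_axis`.
#' @param meta Metadata list carried through.
#' @return An [ftir_spectrum()] on a descending axis.
#' @export
canonicalize_axis <- function(raw_axis, raw_values, meta = list()) {
  if (length(raw_axis) != length(raw_values))
    stop_shape("axis length (%d) != value length (%d)",
               length(raw_axis), length(raw_values))
  d <- diff(as.double(raw_axis))
  if (length(d) == 0L || any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop_axis("axis must be strictly monotone")
  if (d[1] > 0) { raw_axis <- rev(raw_axis); raw_values <- rev(raw_values) }
  ftir_spectrum(wn_axis(raw_axis), raw_values, meta)
}

## Spectra sets ------------------------------------------------------------

#' A set of spectra sharing one axis
#'
#' Row-wise matrix container used throughout preprocessing and modelling: row
#' `i` of `X` is one spectrum on `axis`. Lighter than a list of
#' [ftir_spectrum()] objects while preserving the shared-axis invariant.
#'
#' @param axis A [wn_axis()].
#' @param X Numeric matrix, `n_spectra x n_wavenumbers`.
#' @param meta Optional data.frame with one row per spectrum.
#' @return An object of class `spectra_set` (fields `axis`, `X`, `meta`).
#' @export
spectra_set <- function(axis, X, meta = NULL) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  X <- as.matrix(X)
  if (ncol(X) != length(axis_values(axis)))
    stop_shape("spectra have %d points but axis has %d", ncol(X),
               length(axis_values(axis)))
  if (!is.null(meta) && nrow(meta) != nrow(X))
    stop_shape("meta rows != spectra rows")
  structure(list(axis = axis, X = X, meta = meta), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavenumbers\n", nrow(x$X), ncol(x$X)))
  invisible(x)
}

## Hyperspectral image -----------------------------------------------------

#' Construct a hyperspectral image
#'
#' @param axis A [wn_axis()].
#' @param cube Numeric array `rows x cols x n_wavenumbers` of absorbance.
#' @param pixel_size_um Nominal pixel edge length in micrometres.
#' @param labels Optional integer matrix `rows x cols`: -1 background, 0 MC,
#'   1 SubMC, 2 MP (codes follow [layer_levels()] order).
#' @return Object of class `hyper_image`.
#' @export
hyper_image <- function(axis, cube, pixel_size_um = 11, labels = NULL) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  if (length(dim(cube)) != 3L) stop_shape("cube must be rows x cols x wavenumbers")
  if (dim(cube)[3] != length(axis_values(axis)))
    stop_shape("cube wavenumber dimension (%d) != axis length (%d)",
               dim(cube)[3], length(axis_values(axis)))
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (!all(dim(labels) == dim(cube)[1:2]))
      stop_shape("labels grid must match cube rows x cols")
    if (!all(labels %in% c(-1L, 0L, 1L, 2L)))
      stop_config("labels must be -1 (background), 0 (MC), 1 (SubMC), 2 (MP)")
    storage.mode(labels) <- "integer"
  }
  structure(list(axis = axis, cube = cube, pixel_size_um = pixel_size_um,
                 labels = labels), class = "hyper_image")
}

#' @export
print.hyper_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyper_image> %d x %d pixels x %d wavenumbers%s\n",
              d[1], d[2], d[3], if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

# Layer name <-> integer label code used in the labels grid.
layer_code <- function(layer) match(layer, layer_levels()) - 1L
layer_name <- function(code) c("background", layer_levels())[code + 2L]

# Flatten the cube to a pixel x wavenumber matrix (row-major over the grid:
# pixel index = (col - 1) * rows + row, i.e. column-major like R arrays).
cube_to_matrix <- function(image) {
  d <- dim(image$cube)
  matrix(image$cube, nrow = d[1] * d[2], ncol = d[3])
}

## Cohort ------------------------------------------------------------------

#' Construct one cohort sample record
#'
#' A record holds the averaged representative spectra for one imaged section
#' of one animal in one bowel-wall layer, plus its severity label. Records
#' (not pixels) are the statistical unit throughout quantification and
#' classification.
#'
#' @param animal_id,section_id Character identifiers.
#' @param layer One of `"MC"`, `"SubMC"`, `"MP"`, `"ALL"`.
#' @param severity One of `"control"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param spectra A [spectra_set()] of the record's representative spectra.
#' @return Object of class `sample_record`.
#' @export
sample_record <- function(animal_id, section_id, layer, severity, spectra) {
  check_layer(layer, allow_all = TRUE)
  check_severity(severity)
  if (!inherits(spectra, "spectra_set")) stop_config("spectra must be a spectra_set")
  structure(list(animal_id = as.character(animal_id),
                 section_id = as.character(section_id),
                 layer = layer, severity = severity, spectra = spectra),
            class = "sample_record")
}

#' Construct a cohort of sample records
#'
#' @param records List of [sample_record()] objects, all sharing one axis.
#' @return Object of class `cohort_set` with fields `records` and `axis`.
#' @export
cohort_set <- function(records) {
  if (length(records) == 0L) stop_config("cohort needs at least one record")
  ax <- records[[1]]$spectra$axis
  for (r in records) {
    if (!isTRUE(all.equal(axis_values(r$spectra$axis), axis_values(ax),
                          tolerance = 1e-12)))
      stop_axis("all records must share the cohort axis")
  }
  structure(list(records = records, axis = ax), class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  sev <- vapply(x$records, function(r) r$severity, "")
  cat(sprintf("<cohort_set> %d records (%s)\n", length(x$records),
              paste(sprintf("%s: %d", names(table(sev)), table(sev)),
                    collapse = ", ")))
  invisible(x)
}

#' Summarise a cohort as a metadata table
#'
#' @param cohort A [cohort_set()].
#' @return data.frame with one row per record: animal_id, section_id, layer,
#'   severity, n_spectra.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort$records, function(r)
    data.frame(animal_id = r$animal_id, section_id = r$section_id,
               layer = r$layer, severity = r$severity,
               n_spectra = nrow(r$spectra$X))))
}

# Select records by layer and optionally severity classes.
cohort_subset <- function(cohort, layer = NULL, classes = NULL) {
  keep <- vapply(cohort$records, function(r) {
    (is.null(layer) || identical(layer, "ALL") || r$layer == layer) &&
      (is.null(classes) || r$severity %in% classes)
  }, TRUE)
  cohort$records[keep]
}
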
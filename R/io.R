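## Readers/writers for hyperspectral cubes, cohort tables and single spectra.
##
## Cube container: "csv_long" text dialect with header
## row,col,wavenumber,absorbance (one line per pixel x wavenumber), plus
## optional sidecar columns label and pixel_size_um carried in a JSON header
## comment line. Values round-trip within 1e-9 (text precision 17 digits).

#' Write a hyperspectral image to disk
#'
#' @param image A [hyper_image()].
#' @param path Output file path.
#' @param format Container dialect; `"csv_long"` (text) is supported.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, format = "csv_long") {
  if (!identical(format, "csv_long"))
    stop_format("unsupported cube format '%s' (supported: csv_long)", format)
  d <- dim(image$cube)
  v <- axis_values(image$axis)
  hdr <- jsonlite::toJSON(list(rows = d[1], cols = d[2], n_wn = d[3],
                               pixel_size_um = image$pixel_size_um,
                               has_labels = !is.null(image$labels)),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines("row,col,wavenumber,absorbance,label", con)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  lab <- if (is.null(image$labels)) rep(NA_integer_, d[1] * d[2])
         else as.vector(image$labels)
  # one block of K lines per pixel, wavenumbers in axis order
  for (p in seq_len(nrow(rc))) {
    y <- image$cube[rc$row[p], rc$col[p], ]
    writeLines(sprintf("%d,%d,%.17g,%.17g,%s", rc$row[p], rc$col[p], v, y,
                       ifelse(is.na(lab[p]), "", as.character(lab[p]))), con)
  }
  invisible(path)
}

#' Read a hyperspectral image from disk
#'
#' @param path File written by [write_cube()] (or any long-format CSV with
#'   columns row, col, wavenumber, absorbance and optionally label).
#' @param format Container dialect; `"csv_long"` is supported.
#' @return A [hyper_image()].
#' @export
read_cube <- function(path, format = "csv_long") {
  if (!identical(format, "csv_long"))
    stop_format("unsupported cube format '%s' (supported: csv_long)", format)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.csv(path, skip = skip, check.names = TRUE)
  need <- c("row", "col", "wavenumber", "absorbance")
  if (!all(need %in% names(df)))
    stop_format("csv_long cube requires columns %s", paste(need, collapse = ", "))
  rows <- max(df$row); cols <- max(df$col)
  wn <- sort(unique(df$wavenumber), decreasing = TRUE)
  k <- length(wn)
  if (nrow(df) != rows * cols * k)
    stop_shape("ragged cube: %d rows for %d x %d pixels x %d wavenumbers",
               nrow(df), rows, cols, k)
  cube <- array(NA_real_, c(rows, cols, k))
  idx <- cbind(df$row, df$col, match(df$wavenumber, wn))
  cube[idx] <- df$absorbance
  if (anyNA(cube)) stop_shape("ragged cube: missing pixel/wavenumber entries")
  labels <- NULL
  if ("label" %in% names(df) && !all(is.na(df$label))) {
    labels <- matrix(NA_integer_, rows, cols)
    labels[cbind(df$row, df$col)] <- as.integer(df$label)
    if (anyNA(labels)) labels <- NULL
  }
  hyper_image(wn_axis(wn), cube, pixel_size_um = .cube_pixel_size(first), labels = labels)
}

.cube_pixel_size <- function(header_line) {
  if (!startsWith(header_line, "#")) return(11)
  h <- tryCatch(jsonlite::fromJSON(sub("^#\\s*", "", header_line)),
                error = function(e) NULL)
  if (is.null(h$pixel_size_um)) 11 else h$pixel_size_um
}

## Cohort tables -----------------------------------------------------------

#' Write a cohort to a directory of CSV files
#'
#' Writes `cohort.csv` (columns animal_id, section_id, layer, severity,
#' spectrum_file) plus one wide CSV per record (first column `wavenumber`,
#' one column per representative spectrum).
#'
#' @param cohort A [cohort_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort_table(cohort)
  tab$spectrum_file <- sprintf("record_%03d.csv", seq_len(nrow(tab)))
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    out <- data.frame(wavenumber = axis_values(r$spectra$axis))
    S <- t(r$spectra$X)
    colnames(S) <- sprintf("s%03d", seq_len(ncol(S)))
    utils::write.csv(format(cbind(out, S), digits = 17, trim = TRUE),
                     file.path(dir, tab$spectrum_file[i]), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(tab[, c("animal_id", "section_id", "layer", "severity",
                           "spectrum_file")],
                   file.path(dir, "cohort.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv` and the per-record files.
#' @return A [cohort_set()].
#' @export
read_cohort <- function(dir) {
  idx_path <- file.path(dir, "cohort.csv")
  if (!file.exists(idx_path)) stop_format("missing cohort.csv in %s", dir)
  tab <- utils::read.csv(idx_path, colClasses = "character")
  need <- c("animal_id", "section_id", "layer", "severity", "spectrum_file")
  if (!all(need %in% names(tab)))
    stop_format("cohort.csv requires columns %s", paste(need, collapse = ", "))
  records <- lapply(seq_len(nrow(tab)), function(i) {
    df <- utils::read.csv(file.path(dir, tab$spectrum_file[i]))
    if (!"wavenumber" %in% names(df)) stop_format("record file lacks wavenumber column")
    ax <- wn_axis(df$wavenumber)
    X <- t(as.matrix(df[, setdiff(names(df), "wavenumber"), drop = FALSE]))
    sample_record(tab$animal_id[i], tab$section_id[i], tab$layer[i],
                  tab$severity[i], spectra_set(ax, X))
  })
  cohort_set(records)
}

## JCAMP-DX ----------------------------------------------------------------

#' Write a single spectrum as JCAMP-DX (XYDATA, AFFN)
#'
#' Minimal JCAMP-DX 4.24 writer for fixtures and interchange: plain AFFN
#' `(X++(Y..Y))` tables, no compression.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param path Output path.
#' @param title Spectrum title.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spectrum, path, title = "spectroinflame spectrum") {
  v <- axis_values(spectrum$axis)
  y <- spectrum$absorbance
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.17g", v[1]), sprintf("##LASTX=%.17g", v[length(v)]),
    sprintf("##NPOINTS=%d", length(v)),
    "##XYDATA=(X++(Y..Y))"
  ), con)
  # 4 Y values per line, AFFN
  for (i in seq(1L, length(v), by = 4L)) {
    j <- min(i + 3L, length(v))
    writeLines(paste(c(sprintf("%.17g", v[i]), sprintf("%.17g", y[i:j])),
                     collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

#' Read a JCAMP-DX spectrum written in AFFN XYDATA form
#'
#' @param path JCAMP-DX file.
#' @return An [ftir_spectrum()]; the title is kept in `meta$title`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(sprintf("^##%s=", key), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(sprintf("^##%s=", key), "", hit[1])
  }
  npt <- as.integer(get_field("NPOINTS"))
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0L) stop_format("no XYDATA block in %s", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) stop_format("unterminated XYDATA block")
  xf <- as.double(get_field("XFACTOR") %||% "1")
  yf <- as.double(get_field("YFACTOR") %||% "1")
  xs <- c(); ys <- c()
  for (ln in lines[(start[1] + 1L):(end - 1L)]) {
    vals <- as.double(strsplit(trimws(ln), "\\s+")[[1]])
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (!is.null(npt) && !is.na(npt) && length(ys) != npt)
    stop_format("NPOINTS=%d but %d Y values read", npt, length(ys))
  firstx <- as.double(get_field("FIRSTX")) * xf
  lastx <- as.double(get_field("LASTX")) * xf
  axis <- seq(firstx, lastx, length.out = length(ys))
  canonicalize_axis(axis, ys * yf, meta = list(title = get_field("TITLE")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
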
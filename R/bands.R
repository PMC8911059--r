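## Biochemical band windows used for integrated-area quantification.

#' Define a named integration window
#'
#' @param name Band name.
#' @param high,low Window bounds in cm^-1, `high > low`. Selection of axis
#'   points inside a window is closed on both ends.
#' @return Object of class `band_definition`.
#' @export
band_definition <- function(name, high, low) {
  if (!(is.numeric(high) && is.numeric(low) && high > low))
    stop_config("band window must satisfy high > low (got %s, %s)", high, low)
  structure(list(name = name, high = as.double(high), low = as.double(low)),
            class = "band_definition")
}

#' Built-in biochemical band table
#'
#' Integration windows for the tissue components quantified from the
#' fingerprint region: amide I (1700-1600) and amide II (1580-1510) for
#' protein, the collagen triplet region (1300-1200), glycogen (1250-1000),
#' RNA (1120-1080 around the 1115 cm^-1 ribose band) and DNA (979-948 around
#' the 960 cm^-1 deoxyribose band).
#'
#' @return Named list of [band_definition()] objects.
#' @export
default_band_table <- function() {
  list(
    amide_I  = band_definition("amide_I", 1700, 1600),
    amide_II = band_definition("amide_II", 1580, 1510),
    collagen = band_definition("collagen", 1300, 1200),
    glycogen = band_definition("glycogen", 1250, 1000),
    rna      = band_definition("rna", 1120, 1080),
    dna      = band_definition("dna", 979, 948)
  )
}

# Indices of axis points inside the closed window [low, high].
band_index <- function(axis, band) {
  v <- axis_values(axis)
  idx <- which(v >= band$low & v <= band$high)
  if (length(idx) == 0L)
    stop_range("band %s (%g-%g cm^-1) contains no axis points",
               band$name, band$high, band$low)
  idx
}
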
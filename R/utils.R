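#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

## Condition helpers -------------------------------------------------------

# All package errors carry a subclass so callers (and tests) can match on the
# failure mode rather than on message text.
ftir_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "spectroinflame_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_axis       <- function(msg, ...) ftir_stop("ftir_axis_error", msg, ...)
stop_shape      <- function(msg, ...) ftir_stop("ftir_shape_error", msg, ...)
stop_config     <- function(msg, ...) ftir_stop("ftir_config_error", msg, ...)
stop_range      <- function(msg, ...) ftir_stop("ftir_range_error", msg, ...)
stop_format     <- function(msg, ...) ftir_stop("ftir_format_error", msg, ...)
stop_degenerate <- function(msg, ...) ftir_stop("ftir_degenerate_error", msg, ...)
stop_samplesize <- function(msg, ...) ftir_stop("ftir_samplesize_error", msg, ...)
stop_classabsent<- function(msg, ...) ftir_stop("ftir_classabsent_error", msg, ...)
stop_fold       <- function(msg, ...) ftir_stop("ftir_fold_error", msg, ...)
stop_emptytissue<- function(msg, ...) ftir_stop("ftir_emptytissue_error", msg, ...)

## Vocabularies ------------------------------------------------------------

#' Closed vocabularies for bowel-wall layers and colitis severity
#'
#' The three anatomical layers analysed separately are the mucosa (`"MC"`),
#' submucosa (`"SubMC"`) and muscularis propria (`"MP"`); `"ALL"` denotes
#' pooled layers in classification tasks. Severity follows the chemically
#' induced colitis grading `control < mild < moderate < severe`.
#'
#' @return Character vectors of the admissible values, in canonical order.
#' @export
layer_levels <- function() c("MC", "SubMC", "MP")

#' @rdname layer_levels
#' @export
severity_levels <- function() c("control", "mild", "moderate", "severe")

check_layer <- function(layer, allow_all = FALSE) {
  ok <- c(layer_levels(), if (allow_all) "ALL")
  if (!(is.character(layer) && length(layer) == 1L && layer %in% ok))
    stop_config("layer must be one of %s", paste(ok, collapse = ", "))
  layer
}

check_severity <- function(severity) {
  if (!(is.character(severity) && length(severity) == 1L &&
        severity %in% severity_levels()))
    stop_config("severity must be one of %s",
                paste(severity_levels(), collapse = ", "))
  severity
}

## Seeds -------------------------------------------------------------------

#' Derive a child seed from a parent seed and a name path
#'
#' Deterministic multiply-and-add hashing of the name components onto the
#' parent seed, so every pipeline stage (and every animal/section/layer in the
#' synthetic generator) draws from an independently reproducible stream:
#' adding records to one branch never perturbs another branch's draws.
#'
#' @param seed Integer parent seed.
#' @param ... Character or numeric name components (e.g. stage, animal id).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime below 2^31
  h <- as.double(seed %% m)
  for (part in list(...)) {
    for (code in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

## Numeric helpers ---------------------------------------------------------

# Trapezoidal integral of y over |x| for an ordered (either direction) axis.
trapz_abs <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * abs(diff(x)))
}

is_uniform_axis <- function(values, rel_tol = 1e-6) {
  d <- diff(values)
  span <- mean(abs(d))
  span > 0 && all(abs(d - mean(d)) <= rel_tol * span)
}
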
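## Synthetic hyperspectral colitis generator.
##
## Spectra are sums of Gaussian absorbance bands whose amplitudes carry a
## layer signature (mucosa MC, submucosa SubMC, muscularis propria MP) and a
## severity effect (control -> severe), plus a random smooth quadratic
## baseline per pixel and iid Gaussian noise:
##
##   A(v) = sum_b amp_b * m_layer(b) * m_sev(b) * (1 + jitter_b) * g_b(v)
##          + baseline(v) + eps(v)
##
## Severity moves protein, collagen and nucleic-acid bands up and glycogen
## down, with adjacent classes overlapping so that middle severities are the
## hardest to separate.

#' Default Gaussian band specifications
#'
#' Band centres follow the tissue assignments of the fingerprint region
#' (amide I alpha-helix 1650 / beta-sheet 1635, amide II 1545, protein 1481,
#' lipid ester 1739, collagen triplet 1280/1230/1200, glycogen 1151/1076/1028,
#' RNA 1115, DNA 960 cm^-1); widths and base amplitudes are generator
#' defaults. The `group` column ties each band to the severity effect acting
#' on it.
#'
#' @return data.frame with columns name, center, sigma, amplitude, group.
#' @export
default_band_specs <- function() {
  data.frame(
    name = c("amide_I_alpha", "amide_I_beta", "amide_II", "protein_1481",
             "lipid_ester", "collagen_1280", "collagen_1230", "collagen_1200",
             "glycogen_1151", "glycogen_1076", "glycogen_1028", "rna_1115",
             "dna_960"),
    center = c(1650, 1635, 1545, 1481, 1739, 1280, 1230, 1200,
               1151, 1076, 1028, 1115, 960),
    sigma = c(16, 14, 14, 10, 10, 10, 12, 9, 10, 14, 12, 9, 8),
    amplitude = c(1.0, 0.5, 0.6, 0.1, 0.08, 0.15, 0.2, 0.12,
                  0.15, 0.25, 0.2, 0.08, 0.07),
    group = c("protein", "protein", "protein", "protein", "lipid",
              "collagen", "collagen", "collagen",
              "glycogen", "glycogen", "glycogen", "rna", "dna"),
    stringsAsFactors = FALSE
  )
}

#' Default per-layer band multipliers
#'
#' Encodes the layer signatures: amide I alpha-helix dominant in MC/MP with
#' the beta-sheet conformation dominant in SubMC; the collagen triplet
#' strongest in SubMC (collagenous extracellular matrix); glycogen highest in
#' MC (mucin-producing goblet cells); nucleic acids depleted in MP; overall
#' protein greatest in MP.
#'
#' @return Matrix `bands x layers` of non-negative multipliers.
#' @export
default_layer_chemistry <- function() {
  bands <- default_band_specs()$name
  m <- matrix(1, nrow = length(bands), ncol = 3,
              dimnames = list(bands, layer_levels()))
  m["amide_I_alpha", ] <- c(1.00, 0.40, 1.10)
  m["amide_I_beta", ]  <- c(0.30, 1.00, 0.30)
  m["amide_II", ]      <- c(0.90, 0.80, 1.10)
  m["protein_1481", ]  <- c(0.90, 0.80, 1.10)
  m["lipid_ester", ]   <- c(1.00, 0.90, 1.00)
  m[c("collagen_1280", "collagen_1230", "collagen_1200"), ] <-
    matrix(rep(c(0.50, 1.50, 0.60), each = 3), 3, byrow = FALSE)
  m[c("glycogen_1151", "glycogen_1076", "glycogen_1028"), ] <-
    matrix(rep(c(1.40, 0.70, 0.60), each = 3), 3, byrow = FALSE)
  m["rna_1115", ]      <- c(1.00, 0.90, 0.50)
  m["dna_960", ]       <- c(1.00, 1.00, 0.30)
  m
}

#' Default severity effect multipliers per biochemical group
#'
#' Direction of effect: protein, collagen, DNA and RNA increase with severity
#' while glycogen decreases. Magnitudes are generator defaults chosen so that
#' adjacent severity classes overlap (mild and moderate are the hardest to
#' separate).
#'
#' @return Matrix `groups x severities` of non-negative multipliers.
#' @export
default_severity_effects <- function() {
  m <- rbind(
    protein  = c(1.00, 1.15, 1.30, 1.50),
    collagen = c(1.00, 1.10, 1.20, 1.35),
    dna      = c(1.00, 1.20, 1.45, 1.80),
    rna      = c(1.00, 1.20, 1.45, 1.80),
    glycogen = c(1.00, 0.90, 0.75, 0.60),
    lipid    = c(1.00, 1.00, 1.00, 1.00)
  )
  colnames(m) <- severity_levels()
  m
}

#' Generator configuration
#'
#' @param high,low,spacing Wavenumber axis parameters in cm^-1 (default
#'   1900 -> 700 at 4 cm^-1 point spacing, matching 8 cm^-1 resolution
#'   acquisition with the usual two-fold digitization).
#' @param bands data.frame as [default_band_specs()].
#' @param layer_chemistry Matrix `bands x layers` of multipliers.
#' @param severity_effects Matrix `groups x severities` of multipliers.
#' @param baseline_amplitude Scale (AU) of the random smooth per-pixel
#'   baseline (quadratic + linear tilt).
#' @param noise_sd Per-point iid Gaussian noise sd (AU).
#' @param amplitude_jitter_cv Coefficient of variation of the per-band
#'   amplitude jitter within a spectrum.
#' @param animal_sd Standard deviation of the animal-level shared amplitude
#'   effect (log-scale multiplier), correlating spectra within an animal.
#' @param seed Base seed fixing the full output stream.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(high = 1900, low = 700, spacing = 4,
                             bands = default_band_specs(),
                             layer_chemistry = default_layer_chemistry(),
                             severity_effects = default_severity_effects(),
                             baseline_amplitude = 0.1,
                             noise_sd = 0.005,
                             amplitude_jitter_cv = 0.08,
                             animal_sd = 0.05,
                             seed = 1L) {
  if (noise_sd < 0 || amplitude_jitter_cv < 0 || animal_sd < 0 ||
      baseline_amplitude < 0)
    stop_config("noise_sd, jitter cv, animal_sd, baseline amplitude must be >= 0")
  if (any(bands$sigma <= 0) || any(bands$amplitude < 0))
    stop_config("band sigma must be > 0 and amplitude >= 0")
  if (any(bands$center > high) || any(bands$center < low))
    stop_config("band centers must lie within the axis range")
  if (!setequal(rownames(layer_chemistry), bands$name))
    stop_config("layer_chemistry rows must match band names")
  if (any(layer_chemistry < 0) || any(severity_effects < 0))
    stop_config("multipliers must be non-negative")
  if (!all(unique(bands$group) %in% rownames(severity_effects)))
    stop_config("severity_effects lacks groups: %s",
                paste(setdiff(unique(bands$group), rownames(severity_effects)),
                      collapse = ", "))
  .check_layer_separation(bands, layer_chemistry)
  .check_severity_monotone(severity_effects)
  axis <- wn_axis(seq(high, low, by = -abs(spacing)))
  structure(list(axis = axis, bands = bands,
                 layer_chemistry = layer_chemistry[bands$name, , drop = FALSE],
                 severity_effects = severity_effects,
                 baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 animal_sd = animal_sd, seed = as.integer(seed)),
            class = "generator_config")
}

# Layers must stay mutually distinguishable: for every layer pair, at least
# one band multiplier differs by >= 20% (relative to the larger value).
.check_layer_separation <- function(bands, chem) {
  ll <- colnames(chem)
  for (i in seq_along(ll)) for (j in seq_along(ll)) {
    if (i >= j) next
    a <- chem[, i]; b <- chem[, j]
    rel <- abs(a - b) / pmax(pmax(a, b), .Machine$double.eps)
    if (!any(rel >= 0.20))
      stop_config("layers %s and %s differ by < 20%% in every band",
                  ll[i], ll[j])
  }
}

# Severity effects must be monotone in the stated direction of effect.
.check_severity_monotone <- function(eff) {
  up <- intersect(c("protein", "collagen", "dna", "rna"), rownames(eff))
  for (g in up) if (is.unsorted(eff[g, ]))
    stop_config("severity effect for %s must be non-decreasing", g)
  if ("glycogen" %in% rownames(eff) && is.unsorted(rev(eff["glycogen", ])))
    stop_config("severity effect for glycogen must be non-increasing")
}

## Core spectrum synthesis -------------------------------------------------

# Gaussian band basis: K x B matrix evaluated on the config axis.
band_basis <- function(config) {
  v <- axis_values(config$axis)
  B <- exp(-outer(v, config$bands$center, "-")^2 /
             rep(2 * config$bands$sigma^2, each = length(v)))
  colnames(B) <- config$bands$name
  B
}

# Expected (noiseless, baseline-free) band amplitudes for a layer/severity.
band_amplitudes <- function(config, layer, severity) {
  m_layer <- config$layer_chemistry[, layer]
  m_sev <- config$severity_effects[config$bands$group, severity]
  config$bands$amplitude * m_layer * m_sev
}

# Random smooth baseline: b0 + b1*u + b2*u^2 on u in [0, 1] over the axis,
# coefficients uniform within the configured amplitude scale.
.random_baselines <- function(config, n) {
  v <- axis_values(config$axis)
  u <- (v - min(v)) / (max(v) - min(v))
  amp <- config$baseline_amplitude
  b0 <- stats::runif(n, 0, amp)
  b1 <- stats::runif(n, -amp / 2, amp / 2)
  b2 <- stats::runif(n, 0, amp)
  cbind(b0, b1, b2) %*% rbind(rep(1, length(u)), u, u^2)
}

# n spectra for one (layer, severity); animal_effect is a shared log-scale
# amplitude multiplier. Uses the current RNG stream.
.synth_matrix <- function(config, layer, severity, n, animal_effect = 0) {
  G <- band_basis(config)
  amps <- band_amplitudes(config, layer, severity)
  nb <- length(amps)
  jit <- matrix(stats::rnorm(n * nb, 0, config$amplitude_jitter_cv), n, nb)
  A <- pmax(rep(amps, each = n) * (1 + jit), 0) * exp(animal_effect)
  X <- A %*% t(G) + .random_baselines(config, n)
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X))
  X
}

#' Synthesize a single tissue spectrum
#'
#' @param config A [generator_config()].
#' @param layer,severity Layer and severity class.
#' @param seed Seed for this spectrum's draws (jitter, baseline, noise);
#'   defaults to the config seed.
#' @return An [ftir_spectrum()] with the generating labels in `meta`.
#' @export
synth_spectrum <- function(config, layer, severity, seed = config$seed) {
  check_layer(layer); check_severity(severity)
  X <- withr::with_seed(seed, .synth_matrix(config, layer, severity, 1L))
  ftir_spectrum(config$axis, X[1, ],
                meta = list(layer = layer, severity = severity))
}

## Image synthesis ---------------------------------------------------------

#' Synthesize a striped labelled hyperspectral image
#'
#' The tissue is laid out as three vertical stripes (MC | SubMC | MP across
#' the columns) with an optional background margin of rows at the top and
#' bottom. Background pixels contain baseline and noise only.
#'
#' @param config A [generator_config()].
#' @param rows,cols Grid size of the tissue area.
#' @param stripes Integer vector of 3 stripe widths (columns) for MC, SubMC,
#'   MP; must sum to `cols`, all >= 1.
#' @param severity Severity class of the whole section.
#' @param margin Background rows added above and below the tissue.
#' @param seed Seed for the image's draws.
#' @return A labelled [hyper_image()].
#' @export
synth_image <- function(config, rows = 30, cols = 30,
                        stripes = rep(cols %/% 3, 3), severity = "control",
                        margin = 0, seed = config$seed) {
  check_severity(severity)
  stripes <- as.integer(stripes)
  if (length(stripes) != 3L || any(stripes < 1L))
    stop_config("stripes must be 3 widths, all >= 1")
  if (sum(stripes) != cols)
    stop_config("stripe widths must sum to cols (%d != %d)", sum(stripes), cols)
  total_rows <- rows + 2L * margin
  labels <- matrix(-1L, total_rows, cols)
  col_layer <- rep(0:2, times = stripes)
  labels[margin + seq_len(rows), ] <- matrix(col_layer, rows, cols, byrow = TRUE)
  k <- length(axis_values(config$axis))
  cube <- array(0, c(total_rows, cols, k))
  withr::with_seed(seed, {
    for (code in c(-1L, 0L, 1L, 2L)) {
      idx <- which(labels == code)
      if (length(idx) == 0L) next
      X <- if (code < 0L) {
        .random_baselines(config, length(idx)) +
          matrix(stats::rnorm(length(idx) * k, 0, config$noise_sd),
                 length(idx))
      } else {
        .synth_matrix(config, layer_name(code), severity, length(idx))
      }
      for (j in seq_along(idx)) {
        rc <- arrayInd(idx[j], dim(labels))
        cube[rc[1], rc[2], ] <- X[j, ]
      }
    }
  })
  hyper_image(config$axis, cube, labels = labels)
}

## Cohort synthesis --------------------------------------------------------

#' Synthesize a labelled cohort of sample records
#'
#' Generates `n_animals_per_class[s] * sections_per_animal` records per
#' severity `s` and bowel layer, each holding `spectra_per_layer`
#' representative spectra. An animal-level random effect (shared log-amplitude
#' multiplier) correlates all spectra from one animal. Seeds are derived
#' hierarchically (animal -> section -> layer) so the draws for one animal
#' never depend on how many other animals are generated.
#'
#' @param config A [generator_config()].
#' @param n_animals_per_class Named integer vector, e.g.
#'   `c(control = 3, severe = 3)`.
#' @param sections_per_animal Sections imaged per animal.
#' @param spectra_per_layer Representative spectra per record.
#' @param layers Layers to generate (default all three).
#' @param seed Base seed (defaults to the config seed).
#' @return A [cohort_set()].
#' @export
synth_cohort <- function(config, n_animals_per_class = c(control = 3, mild = 3,
                                                         moderate = 3, severe = 3),
                         sections_per_animal = 2, spectra_per_layer = 25,
                         layers = layer_levels(), seed = config$seed) {
  if (length(n_animals_per_class) == 0L)
    stop_config("n_animals_per_class must name at least one severity class")
  if (is.null(names(n_animals_per_class)) ||
      !all(names(n_animals_per_class) %in% severity_levels()))
    stop_config("n_animals_per_class names must be severity classes")
  if (any(n_animals_per_class < 1L) || sections_per_animal < 1L ||
      spectra_per_layer < 1L)
    stop_config("all counts must be >= 1")
  for (l in layers) check_layer(l)
  records <- list()
  for (sev in names(n_animals_per_class)) {
    for (a in seq_len(n_animals_per_class[[sev]])) {
      animal_id <- sprintf("%s_a%02d", sev, a)
      animal_effect <- withr::with_seed(
        derive_seed(seed, "animal", animal_id),
        stats::rnorm(1, 0, config$animal_sd))
      for (s in seq_len(sections_per_animal)) {
        section_id <- sprintf("%s_s%d", animal_id, s)
        for (l in layers) {
          X <- withr::with_seed(
            derive_seed(seed, "record", section_id, l),
            .synth_matrix(config, l, sev, spectra_per_layer, animal_effect))
          records[[length(records) + 1L]] <- sample_record(
            animal_id, section_id, l, sev, spectra_set(config$axis, X))
        }
      }
    }
  }
  cohort_set(records)
}
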
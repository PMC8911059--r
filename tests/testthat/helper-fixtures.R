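# Shared fixtures, built once per test run. Sizes are kept small; the
# statistical properties they exercise do not depend on cohort scale.

gen_default <- generator_config()

# Noise-free, jitter-free generator for analytic checks.
gen_clean <- generator_config(noise_sd = 0, amplitude_jitter_cv = 0,
                              animal_sd = 0, baseline_amplitude = 0)

# A single-band generator on an axis containing the band centre exactly.
single_band_config <- function(center = 1650, sigma = 15, amplitude = 1,
                               spacing = 5, noise_sd = 0, jitter = 0,
                               baseline = 0, severity_ratio = 1.5) {
  bands <- data.frame(name = "peak", center = center, sigma = sigma,
                      amplitude = amplitude, group = "protein",
                      stringsAsFactors = FALSE)
  chem <- matrix(c(1, 0.5, 1.5), nrow = 1,
                 dimnames = list("peak", layer_levels()))
  eff <- matrix(rep(1, 4), nrow = 1, dimnames = list("protein", severity_levels()))
  eff["protein", "severe"] <- severity_ratio
  generator_config(high = 1900, low = 700, spacing = spacing, bands = bands,
                   layer_chemistry = chem, severity_effects = eff,
                   baseline_amplitude = baseline, noise_sd = noise_sd,
                   amplitude_jitter_cv = jitter, animal_sd = 0)
}

# Two-class cohort used by the binary chemometrics tests.
binary_cohort <- synth_cohort(gen_default, c(control = 3, severe = 3),
                              sections_per_animal = 2, spectra_per_layer = 5,
                              seed = 2024)

# Striped labelled image with a background margin.
striped_image <- synth_image(gen_default, rows = 15, cols = 15,
                             stripes = c(5, 5, 5), severity = "control",
                             margin = 2, seed = 77)

# Brute-force lower-convex-hull baseline by the pairwise-chord test: a chord
# between points i < j is admissible if it lies on or below every point; the
# baseline at x_k is the maximum admissible chord value covering k (endpoints
# included). Independent of the monotone-chain implementation.
chord_hull_baseline <- function(x, y, tol = 1e-9) {
  n <- length(x)
  base <- rep(-Inf, n)
  base[c(1, n)] <- y[c(1, n)]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slope <- (y[j] - y[i]) / (x[j] - x[i])
      chord <- y[i] + slope * (x - x[i])
      if (all(y >= chord - tol)) {
        seg <- i:j
        base[seg] <- pmax(base[seg], chord[seg])
      }
    }
  }
  base
}
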
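# Synthetic generator: analytic peak model, layer/severity structure,
# hierarchical determinism.

test_that("a single noiseless band reproduces the analytic Gaussian peak", {
  cfg <- single_band_config(center = 1650, sigma = 15, amplitude = 1)
  s <- synth_spectrum(cfg, "MC", "control", seed = 1)
  v <- axis_values(s$axis)
  expect_equal(v[which.max(s$absorbance)], 1650)
  expect_equal(max(s$absorbance), 1.0, tolerance = 1e-9)
  # analytic profile everywhere, not just at the peak
  expect_equal(s$absorbance, exp(-(v - 1650)^2 / (2 * 15^2)), tolerance = 1e-9)
})

test_that("severity multipliers scale bands linearly in the noiseless model", {
  cfg <- single_band_config(severity_ratio = 1.5)
  s_con <- synth_spectrum(cfg, "MC", "control", seed = 4)
  s_sev <- synth_spectrum(cfg, "MC", "severe", seed = 4)
  nz <- s_con$absorbance > 1e-6
  expect_equal(s_sev$absorbance[nz] / s_con$absorbance[nz],
               rep(1.5, sum(nz)), tolerance = 1e-9)
})

test_that("the noiseless spectrum is the sum of its per-band components", {
  s <- synth_spectrum(gen_clean, "SubMC", "moderate", seed = 3)
  v <- axis_values(s$axis)
  bands <- gen_clean$bands
  manual <- rep(0, length(v))
  for (i in seq_len(nrow(bands))) {
    amp <- bands$amplitude[i] *
      gen_clean$layer_chemistry[bands$name[i], "SubMC"] *
      gen_clean$severity_effects[bands$group[i], "moderate"]
    manual <- manual + amp * exp(-(v - bands$center[i])^2 / (2 * bands$sigma[i]^2))
  }
  expect_equal(s$absorbance, manual, tolerance = 1e-12)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- synth_spectrum(gen_default, "MC", "mild", seed = 11)
  b <- synth_spectrum(gen_default, "MC", "mild", seed = 11)
  c <- synth_spectrum(gen_default, "MC", "mild", seed = 12)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c$absorbance))
  co1 <- synth_cohort(gen_default, c(control = 2, severe = 2), 1, 3, seed = 8)
  co2 <- synth_cohort(gen_default, c(control = 2, severe = 2), 1, 3, seed = 8)
  expect_identical(co1$records[[3]]$spectra$X, co2$records[[3]]$spectra$X)
})

test_that("adding animals to one class leaves other animals' draws unchanged", {
  co_small <- synth_cohort(gen_default, c(control = 2, severe = 2), 1, 3, seed = 8)
  co_large <- synth_cohort(gen_default, c(control = 4, severe = 2), 1, 3, seed = 8)
  tab_small <- cohort_table(co_small)
  tab_large <- cohort_table(co_large)
  key <- which(tab_large$animal_id == "severe_a02" & tab_large$layer == "MP")
  key0 <- which(tab_small$animal_id == "severe_a02" & tab_small$layer == "MP")
  expect_identical(co_large$records[[key]]$spectra$X,
                   co_small$records[[key0]]$spectra$X)
})

test_that("striped image layout counts pixels and labels correctly", {
  img <- synth_image(gen_default, rows = 30, cols = 30, stripes = c(10, 10, 10),
                     severity = "control", margin = 0, seed = 1)
  expect_equal(as.vector(table(factor(img$labels, levels = 0:2))),
               rep(300L, 3))
  img_m <- synth_image(gen_default, rows = 10, cols = 9, stripes = c(3, 3, 3),
                       severity = "control", margin = 2, seed = 1)
  expect_equal(sum(img_m$labels == -1L), 2 * 2 * 9)
  expect_error(synth_image(gen_default, rows = 10, cols = 9,
                           stripes = c(0, 5, 4), seed = 1),
               class = "ftir_config_error")
  expect_error(synth_image(gen_default, rows = 10, cols = 9,
                           stripes = c(3, 3, 4), seed = 1),
               class = "ftir_config_error")
})

test_that("stripe chemistry follows the layer signatures", {
  img <- synth_image(gen_clean, rows = 6, cols = 9, stripes = c(3, 3, 3),
                     severity = "control", margin = 2, seed = 2)
  collagen <- default_band_table()$collagen
  areas <- function(code) {
    idx <- which(as.vector(img$labels) == code)
    X <- spectroinflame:::cube_to_matrix(img)[idx, , drop = FALSE]
    mean(spectroinflame:::integrate_band_set(spectra_set(img$axis, X), collagen))
  }
  expect_gt(areas(1L), areas(0L))  # SubMC collagen > MC
  expect_gt(areas(1L), areas(2L))  # SubMC collagen > MP
  # background rows carry no amide-I signal beyond noise
  img_n <- synth_image(gen_default, rows = 6, cols = 9, stripes = c(3, 3, 3),
                       severity = "control", margin = 2, seed = 3)
  bg <- which(as.vector(img_n$labels) == -1L)[1]
  Xbg <- spectroinflame:::cube_to_matrix(img_n)[bg, , drop = FALSE]
  corr <- rubberband_baseline(spectra_set(img_n$axis, Xbg))$corrected
  amide <- integrate_band(ftir_spectrum(img_n$axis, corr$X[1, ]),
                          default_band_table()$amide_I)
  # trapezoid of clipped noise over ~26 points x 4 cm^-1 spacing
  expect_lt(amide, 3 * gen_default$noise_sd * 26 * 4)
})

test_that("cohort counts follow the requested design", {
  co <- synth_cohort(gen_default, c(control = 3, severe = 3), 2, 25, seed = 1)
  tab <- cohort_table(co)
  expect_equal(nrow(tab), 36L)               # 6 animals x 2 sections x 3 layers
  expect_equal(sum(tab$n_spectra), 900L)
  expect_equal(unique(tab$n_spectra), 25L)
  expect_error(synth_cohort(gen_default, c(), 1, 1), class = "ftir_config_error")
  expect_error(synth_cohort(gen_default, c(control = 0, severe = 2), 1, 1),
               class = "ftir_config_error")
})

test_that("animal random effect dominates within-animal variance when large", {
  cfg <- generator_config(animal_sd = 0.3, noise_sd = 0.001,
                          amplitude_jitter_cv = 0.005, baseline_amplitude = 0)
  co <- synth_cohort(cfg, c(control = 6), 1, 6, layers = "MC", seed = 21)
  amide <- default_band_table()$amide_I
  d <- do.call(rbind, lapply(co$records, function(r) {
    areas <- spectroinflame:::integrate_band_set(
      rubberband_baseline(crop_spectrum(r$spectra, 1801, 798))$corrected, amide)
    data.frame(animal = r$animal_id, area = areas)
  }))
  fit <- stats::aov(area ~ animal, data = d)   # one-way ANOVA oracle
  tab <- summary(fit)[[1]]
  expect_gt(tab$`F value`[1], 1)
  expect_lt(tab$`Pr(>F)`[1], 0.01)
})

test_that("expected band areas are monotone in severity in the stated directions", {
  bands <- default_band_table()
  areas <- sapply(severity_levels(), function(sev) {
    s <- synth_spectrum(gen_clean, "MC", sev, seed = 1)
    vapply(bands, function(b) integrate_band(s, b), 0)
  })
  for (up in c("amide_I", "amide_II", "collagen", "dna"))
    expect_false(is.unsorted(areas[up, ]), info = up)
  expect_false(is.unsorted(rev(areas["glycogen", ])))
  # the printed RNA window overlaps the down-going glycogen 1076 band wing,
  # so monotonicity holds for the isolated RNA component, not the raw window
  keep <- gen_clean$bands$group != "glycogen"
  cfg_nogly <- generator_config(
    bands = gen_clean$bands[keep, ],
    layer_chemistry = default_layer_chemistry()[gen_clean$bands$name[keep], ],
    noise_sd = 0, amplitude_jitter_cv = 0, animal_sd = 0,
    baseline_amplitude = 0)
  rna_areas <- vapply(severity_levels(), function(sev)
    integrate_band(synth_spectrum(cfg_nogly, "MC", sev, seed = 1),
                   default_band_table()$rna), 0)
  expect_false(is.unsorted(rna_areas))
})

test_that("config validation rejects inseparable layers and wrong directions", {
  chem <- default_layer_chemistry()
  chem[] <- 1
  expect_error(generator_config(layer_chemistry = chem),
               class = "ftir_config_error")
  eff <- default_severity_effects()
  eff["glycogen", ] <- c(1, 1.1, 1.2, 1.3)
  expect_error(generator_config(severity_effects = eff),
               class = "ftir_config_error")
})
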
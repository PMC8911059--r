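# Preprocessing chain: crop, rubber-band, Savitzky-Golay, SNV, background
# removal, averaging, and the two pipeline modes.

test_that("cropping retains exactly the closed-window axis points", {
  ax <- wn_axis(seq(1900, 700, by = -4))
  s <- ftir_spectrum(ax, seq_along(axis_values(ax)))
  c1 <- crop_spectrum(s, 1801, 798)
  v <- axis_values(c1$axis)
  expect_equal(v[1], 1800)
  expect_equal(v[length(v)], 800)
  expect_equal(length(v), length(seq(1800, 800, by = -4)))
  # closed interval: a point exactly at the bound is kept
  c2 <- crop_spectrum(s, 1800, 800)
  expect_equal(axis_values(c2$axis)[1], 1800)
  # full-range crop is the identity
  c3 <- crop_spectrum(s, 1900, 700)
  expect_equal(c3$absorbance, s$absorbance)
  expect_error(crop_spectrum(s, 500, 400), class = "ftir_range_error")
})

test_that("rubber-band correction vanishes on convex spectra", {
  ax <- wn_axis(seq(1800, 1000, by = -8))
  v <- axis_values(ax)
  conv <- ftir_spectrum(ax, (v / 1000)^2)
  rb <- rubberband_baseline(conv)
  expect_equal(rb$corrected$absorbance, rep(0, length(v)), tolerance = 1e-12)
  expect_equal(rb$baseline$absorbance, conv$absorbance, tolerance = 1e-12)
})

test_that("rubber-band baseline under a single peak is the endpoint chord", {
  ax <- wn_axis(seq(1800, 1000, by = -8))
  v <- axis_values(ax)
  peak <- ftir_spectrum(ax, exp(-(v - 1400)^2 / (2 * 40^2)))
  rb <- rubberband_baseline(peak)
  n <- length(v)
  chord <- peak$absorbance[1] + (peak$absorbance[n] - peak$absorbance[1]) *
    (v - v[1]) / (v[n] - v[1])
  expect_equal(rb$baseline$absorbance, chord, tolerance = 1e-9)
  expect_equal(rb$corrected$absorbance[c(1, n)], c(0, 0))
  expect_true(all(rb$corrected$absorbance >= -1e-12))
})

test_that("rubber-band correction is invariant to added affine baselines", {
  s <- synth_spectrum(gen_default, "MC", "severe", seed = 31)
  v <- axis_values(s$axis)
  shifted <- ftir_spectrum(s$axis, s$absorbance + 0.003 * v - 2.5)
  expect_equal(rubberband_baseline(shifted)$corrected$absorbance,
               rubberband_baseline(s)$corrected$absorbance, tolerance = 1e-9)
  expect_error(rubberband_baseline(ftir_spectrum(wn_axis(c(10, 5)), c(1, 2))),
               class = "ftir_shape_error")
})

test_that("rubber-band equals the brute-force pairwise-chord hull oracle", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    x <- sort(runif(n, 700, 1900))
    y <- cumsum(rnorm(n)) + runif(1, 0, 4) * dnorm(x, mean = runif(1, 900, 1700),
                                                   sd = runif(1, 20, 200))
    base <- spectroinflame:::lower_hull_baseline(x, y)
    expect_equal(base, chord_hull_baseline(x, y), tolerance = 1e-8)
  }
})

test_that("SG filter is exact for polynomials up to its order, everywhere", {
  ax <- wn_axis(seq(1900, 700, by = -4))
  v <- axis_values(ax)
  a <- 4.2e-5; b <- -0.013; cc <- 3.1
  quad <- ftir_spectrum(ax, a * v^2 + b * v + cc)
  d2 <- savitzky_golay(quad, 9, 3, 2)
  expect_equal(d2$absorbance, rep(2 * a, length(v)), tolerance = 1e-8)
  d1 <- savitzky_golay(quad, 9, 3, 1)
  expect_equal(d1$absorbance, 2 * a * v + b, tolerance = 1e-8)
  cubic <- ftir_spectrum(ax, (v / 1000)^3)
  expect_equal(savitzky_golay(cubic, 9, 3, 0)$absorbance, cubic$absorbance,
               tolerance = 1e-8)
})

test_that("SG second derivative of a Gaussian dips at the peak centre", {
  cfg <- single_band_config(center = 1650, sigma = 15, spacing = 5)
  s <- synth_spectrum(cfg, "MC", "control", seed = 1)
  v <- axis_values(s$axis)
  d2 <- savitzky_golay(s, 9, 3, 2)
  expect_lte(abs(v[which.min(d2$absorbance)] - 1650), 5)
  # compare with the analytic second derivative away from the tails
  analytic <- (((v - 1650)^2 / 15^4) - 1 / 15^2) * exp(-(v - 1650)^2 / (2 * 15^2))
  core <- abs(v - 1650) < 60
  expect_equal(d2$absorbance[core], analytic[core], tolerance = 5e-3)
})

test_that("SG rejects invalid configurations", {
  s <- synth_spectrum(gen_default, "MC", "control", seed = 1)
  expect_error(savitzky_golay(s, 8, 3, 2), class = "ftir_config_error")
  expect_error(savitzky_golay(s, 9, 9, 2), class = "ftir_config_error")
  expect_error(savitzky_golay(s, 9, 3, 4), class = "ftir_config_error")
})

test_that("SNV normalises to mean 0 / sd 1, idempotently, affine-invariantly", {
  s <- synth_spectrum(gen_default, "SubMC", "mild", seed = 17)
  z <- snv(s)
  expect_equal(mean(z$absorbance), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$absorbance), 1, tolerance = 1e-12)
  expect_equal(snv(z)$absorbance, z$absorbance, tolerance = 1e-12)
  aff <- ftir_spectrum(s$axis, 3.7 * s$absorbance + 11)
  expect_equal(snv(aff)$absorbance, z$absorbance, tolerance = 1e-9)
  expect_error(snv(ftir_spectrum(s$axis, rep(1, length(s$absorbance)))),
               class = "ftir_degenerate_error")
})

test_that("background removal recovers the true margin and spares tissue", {
  img <- synth_image(generator_config(noise_sd = 0, amplitude_jitter_cv = 0,
                                      animal_sd = 0),
                     rows = 8, cols = 9, stripes = c(3, 3, 3),
                     severity = "control", margin = 2, seed = 12)
  truth <- img$labels
  blind <- hyper_image(img$axis, img$cube, img$pixel_size_um, NULL)
  out <- remove_background(blind, preprocess_config(background_fraction = 0.1))
  expect_identical(out$labels == -1L, truth == -1L)
  zero <- hyper_image(img$axis, array(0, dim(img$cube)))
  expect_error(remove_background(zero), class = "ftir_emptytissue_error")
})

test_that("averaging partitions preserve the grand mean and handle shortfall", {
  s <- synth_spectrum(gen_default, "MC", "control", seed = 3)
  X <- matrix(rep(s$absorbance, 100), nrow = 100, byrow = TRUE)
  same <- average_to_representatives(spectra_set(s$axis, X), 25, seed = 1)
  expect_equal(nrow(same$X), 25L)
  expect_equal(same$X[7, ], s$absorbance, ignore_attr = TRUE)
  # equal-sized bins: grand mean preserved exactly
  set.seed(5)
  Y <- matrix(rnorm(80 * 301), 80)
  reps <- average_to_representatives(spectra_set(s$axis, Y), 20, seed = 2)
  expect_equal(colMeans(reps$X), colMeans(Y), tolerance = 1e-9)
  # fewer pixels than requested representatives: identity
  few <- average_to_representatives(spectra_set(s$axis, Y[1:10, ]), 25, seed = 2)
  expect_equal(nrow(few$X), 10L)
  expect_equal(few$X, Y[1:10, ], ignore_attr = TRUE)
})

test_that("pipeline modes share pixels and meet their output contracts", {
  cfgp <- preprocess_config(n_avg = 12, avg_seed = 4)
  cls <- preprocess_pipeline(striped_image, cfgp, "classification")
  qnt <- preprocess_pipeline(striped_image, cfgp, "quantification")
  expect_equal(nrow(cls$X), 12L)
  expect_equal(nrow(qnt$X), 12L)
  expect_equal(rowMeans(cls$X), rep(0, 12), tolerance = 1e-12)
  expect_equal(apply(cls$X, 1, stats::sd), rep(1, 12), tolerance = 1e-12)
  expect_true(all(qnt$X >= 0))
  expect_equal(attr(cls, "stages"),
               c("crop", "remove_background", "savitzky_golay", "snv",
                 "average_to_representatives", "snv"))
  expect_equal(attr(qnt, "stages")[1:2], attr(cls, "stages")[1:2])
  # deterministic given (image, cfg, seed)
  cls2 <- preprocess_pipeline(striped_image, cfgp, "classification")
  expect_identical(cls$X, cls2$X)
})

test_that("representative multiset is shuffle-independent when bins are pixels", {
  # with n_avg >= n_pixels the seeded shuffle is bypassed, so reordering
  # pixels permutes but never alters the representatives
  img <- synth_image(gen_default, rows = 4, cols = 6, stripes = c(2, 2, 2),
                     severity = "mild", margin = 0, seed = 9)
  cfgp <- preprocess_config(n_avg = 1000)
  reps <- preprocess_pipeline(img, cfgp, "classification")
  perm <- hyper_image(img$axis, img$cube[4:1, , , drop = FALSE],
                      img$pixel_size_um, img$labels[4:1, , drop = FALSE])
  reps_perm <- preprocess_pipeline(perm, cfgp, "classification")
  key <- function(M) sort(apply(round(M, 9), 1, paste, collapse = ","))
  expect_equal(key(reps$X), key(reps_perm$X))
})
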
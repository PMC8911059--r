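## End-to-end workflow: synthesize -> preprocess -> quantify -> PLS-DA ->
## severity ensemble -> layer segmentation, from one seeded configuration.

#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list; every element can be
#' overridden (e.g. loaded from YAML via [read_run_config()]). Stage seeds
#' are derived from `global_seed` by stage-name hashing so each stage is
#' independently reproducible.
#'
#' @param global_seed Integer master seed.
#' @return Named list: `generator`, `preprocess`, `cohort` (counts), `plsda`,
#'   `severity`, `segment`, `global_seed`.
#' @export
default_run_config <- function(global_seed = 1L) {
  list(
    generator = list(noise_sd = 0.005, amplitude_jitter_cv = 0.08,
                     animal_sd = 0.05, baseline_amplitude = 0.1),
    cohort = list(n_animals_per_class = c(control = 3, mild = 3,
                                          moderate = 3, severe = 3),
                  sections_per_animal = 2, spectra_per_layer = 25),
    preprocess = list(),
    plsda = list(classes = c("control", "severe"), layer = "ALL",
                 max_lv = 8, n_blinds = 10),
    severity = list(layer = "SubMC", n_repeats = 10, train_frac = 0.7,
                    variance_target = 0.95, inner_folds = 5),
    segment = list(rows = 24, cols = 24, n_per_class = 10, iterations = 100),
    global_seed = as.integer(global_seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_run_config()].
#'
#' @param path YAML file.
#' @return Run configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(user$global_seed %||% 1L)
  for (sec in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else cfg[[sec]] <- user[[sec]]
  }
  if (!is.null(cfg$cohort$n_animals_per_class))
    cfg$cohort$n_animals_per_class <- unlist(cfg$cohort$n_animals_per_class)
  cfg
}

stage_artifact <- function(manifest, name, value) {
  manifest$stages[[name]] <- list(hash = rlang::hash(value))
  manifest
}

#' Run the full analysis workflow
#'
#' Executes, in order: cohort synthesis, image synthesis, biochemical
#' quantification with Welch tests (severe vs control per band), binary
#' PLS-DA (venetian-blind CV, LV selection, VIP scores, VIP-band Welch
#' follow-up), severity classification by the stacked ensemble with repeated
#' stratified hold-outs, and layer segmentation of an independent image.
#' Identical config and seed reproduce identical results and manifest hashes.
#'
#' @param config A configuration list as [default_run_config()].
#' @param output_dir Optional directory; when given, a JSON report and
#'   manifest are written there.
#' @return List with elements `cohort`, `quantification`, `plsda`,
#'   `severity`, `segmentation` and `manifest` (stage content hashes).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL) {
  seed <- config$global_seed
  manifest <- list(global_seed = seed, stages = list())

  gen <- do.call(generator_config,
                 c(config$generator, list(seed = derive_seed(seed, "generator"))))
  prep <- do.call(preprocess_config, config$preprocess)

  cohort <- synth_cohort(
    gen, n_animals_per_class = config$cohort$n_animals_per_class,
    sections_per_animal = config$cohort$sections_per_animal,
    spectra_per_layer = config$cohort$spectra_per_layer,
    seed = derive_seed(seed, "cohort"))
  manifest <- stage_artifact(manifest, "cohort", cohort)

  # biochemistry: severe-vs-control Welch test per default band, MC layer
  areas <- quantify_cohort(cohort, cfg = prep)
  welch <- lapply(default_band_table(), function(b) {
    wt <- compare_groups(cohort, b, "severe", "control", layer = "MC", cfg = prep)
    data.frame(band = b$name, t_stat = wt$t_stat, p_value = wt$p_value,
               mean_diff = wt$mean_diff)
  })
  quant <- list(areas = areas, welch = do.call(rbind, unname(welch)))
  manifest <- stage_artifact(manifest, "quantification", quant)

  # binary PLS-DA, control vs severe
  pl <- config$plsda
  cm <- cohort_matrix(cohort, layer = pl$layer, classes = pl$classes,
                      cfg = prep, mode = "classification")
  max_lv <- min(pl$max_lv, nrow(cm$X) - 1L, ncol(cm$X))
  curve <- venetian_cv(cm$X, cm$y, max_lv = max_lv, n_blinds = pl$n_blinds,
                       ids = cm$meta$record)
  n_lv <- select_n_lv(curve)
  model <- plsda_fit(cm$X, cm$y, n_lv)
  cv_eval <- plsda_cv_eval(cm$X, cm$y, n_lv, n_blinds = pl$n_blinds,
                           ids = cm$meta$record, positive = "severe")
  vip_tests <- vip_band_tests(cohort, cm$axis, model$vip, threshold = 1,
                              class_a = "severe", class_b = "control",
                              layer = pl$layer, cfg = prep)
  plsda <- list(cv_curve = curve, n_lv = n_lv, vip = model$vip,
                sensitivity = cv_eval$sensitivity,
                specificity = cv_eval$specificity,
                confusion = cv_eval$confusion, vip_band_tests = vip_tests)
  manifest <- stage_artifact(manifest, "plsda", plsda)

  # severity ensemble
  sv <- config$severity
  report <- repeated_holdout(cohort, layer = sv$layer, cfg = prep,
                             n_repeats = sv$n_repeats,
                             train_frac = sv$train_frac,
                             variance_target = sv$variance_target,
                             inner_folds = sv$inner_folds,
                             seed = derive_seed(seed, "severity"))
  manifest <- stage_artifact(manifest, "severity", report)

  # layer segmentation on an independent image
  sg <- config$segment
  img_train <- synth_image(gen, rows = sg$rows, cols = sg$cols,
                           severity = "control", margin = 2,
                           seed = derive_seed(seed, "segment_train"))
  img_test <- synth_image(gen, rows = sg$rows, cols = sg$cols,
                          severity = "control", margin = 2,
                          seed = derive_seed(seed, "segment_test"))
  segmenter <- layer_segmenter_train(img_train, prep,
                                     n_per_class = sg$n_per_class,
                                     iterations = sg$iterations,
                                     seed = derive_seed(seed, "segmenter"))
  pred <- segment_image(segmenter, img_test)
  tissue <- img_test$labels >= 0L
  seg <- list(labels = pred,
              accuracy = mean(pred[tissue] == img_test$labels[tissue]))
  manifest <- stage_artifact(manifest, "segmentation", seg)

  result <- list(cohort = cohort, quantification = quant, plsda = plsda,
                 severity = report, segmentation = seg, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(
      manifest = manifest,
      plsda = list(n_lv = n_lv, sensitivity = cv_eval$sensitivity,
                   specificity = cv_eval$specificity),
      severity = report$per_class,
      segmentation_accuracy = seg$accuracy,
      welch = quant$welch)
    jsonlite::write_json(summary, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
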
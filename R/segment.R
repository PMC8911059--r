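## Hyperspectral layer segmentation: a small single-hidden-layer neural
## network trained on a handful of labelled pixel spectra per bowel layer,
## then applied pixel-wise to whole images.

# Per-pixel classification-mode preprocessing of an image (crop, SG second
# derivative, SNV) keeping the pixel order; no averaging.
preprocess_pixels <- function(image, cfg) {
  idx <- crop_index(image$axis, cfg$crop_high, cfg$crop_low)
  axis <- wn_axis(axis_values(image$axis)[idx])
  X <- cube_to_matrix(image)[, idx, drop = FALSE]
  X <- .savgol_matrix(X, axis, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
  spectra_set(axis, .snv_matrix(X))
}

#' Train the hyperspectral layer segmenter
#'
#' Trains a three-layer (single hidden layer) neural network on exactly
#' `n_per_class` randomly chosen labelled pixel spectra per bowel layer,
#' preprocessed in classification mode, for the stated iteration count.
#'
#' @param image A labelled [hyper_image()].
#' @param cfg A [preprocess_config()].
#' @param n_per_class Training pixels per layer (default 10).
#' @param iterations Training epochs (default 100).
#' @param hidden Hidden-layer width (default 15).
#' @param seed Seed for pixel sampling and weight initialisation.
#' @return Object of class `layer_segmenter` (a `base_classifier` over the
#'   three layer names plus the preprocessing config and axis).
#' @export
layer_segmenter_train <- function(image, cfg = preprocess_config(),
                                  n_per_class = 10, iterations = 100,
                                  hidden = 15, seed = 0L) {
  if (is.null(image$labels)) stop_config("image must carry layer labels")
  lab <- as.vector(image$labels)
  counts <- table(factor(lab[lab >= 0L], levels = 0:2))
  if (any(counts < n_per_class))
    stop_samplesize("need >= %d labelled pixels per layer (have %s)",
                    n_per_class, paste(counts, collapse = ", "))
  pix <- preprocess_pixels(image, cfg)
  train_idx <- withr::with_seed(derive_seed(seed, "sample"), unlist(
    lapply(0:2, function(code) sample(which(lab == code), n_per_class))))
  y <- factor(layer_name(lab[train_idx]), levels = layer_levels())
  spec <- classifier_spec("ann", list(size = hidden, maxit = iterations),
                          seed = derive_seed(seed, "weights"))
  clf <- fit_base(spec, pix$X[train_idx, , drop = FALSE], y)
  structure(list(classifier = clf, cfg = cfg,
                 axis = pix$axis, train_idx = train_idx),
            class = "layer_segmenter")
}

#' Segment a hyperspectral image into bowel layers
#'
#' Applies the trained segmenter pixel-wise (argmax class probability);
#' pixels labelled background in the input stay background.
#'
#' @param segmenter A [layer_segmenter_train()] result.
#' @param image A [hyper_image()] on a compatible axis.
#' @return Integer label matrix `rows x cols` (-1 background, 0 MC, 1 SubMC,
#'   2 MP).
#' @export
segment_image <- function(segmenter, image) {
  pix <- preprocess_pixels(image, segmenter$cfg)
  if (!isTRUE(all.equal(axis_values(pix$axis), axis_values(segmenter$axis),
                        tolerance = 1e-9)))
    stop_axis("image axis incompatible with the segmenter's training axis")
  pred <- predict_class(segmenter$classifier, pix$X)
  labels <- matrix(layer_code(as.character(pred)), dim(image$cube)[1],
                   dim(image$cube)[2])
  if (!is.null(image$labels)) labels[image$labels < 0L] <- -1L
  labels
}
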
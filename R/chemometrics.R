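## PCA, PLS-DA (NIPALS), venetian-blind cross-validation, VIP scores.

#' Build a modelling matrix from a cohort
#'
#' Applies the classification (or quantification) preprocessing chain to
#' every record's representative spectra and stacks them row-wise, with the
#' record-level metadata repeated per row. Preprocessing is strictly
#' per-spectrum, so it can be applied before any train/test split without
#' leakage.
#'
#' @param cohort A [cohort_set()].
#' @param layer `"ALL"` to pool layers, else one of [layer_levels()].
#' @param classes Optional severity classes to retain.
#' @param cfg A [preprocess_config()].
#' @param mode Preprocessing mode (default `"classification"`).
#' @return List: `X` (rows = spectra), `y` (factor of severities), `meta`
#'   (data.frame: animal_id, section_id, layer, severity, record), `axis`.
#' @export
cohort_matrix <- function(cohort, layer = "ALL", classes = NULL,
                          cfg = preprocess_config(),
                          mode = c("classification", "quantification")) {
  mode <- match.arg(mode)
  recs <- cohort_subset(cohort, layer, classes)
  if (length(recs) == 0L) stop_classabsent("no records for layer %s", layer)
  parts <- lapply(recs, function(r) preprocess_record_spectra(r$spectra, cfg, mode))
  X <- do.call(rbind, lapply(parts, function(s) s$X))
  n_per <- vapply(parts, function(s) nrow(s$X), 0L)
  meta <- do.call(rbind, lapply(seq_along(recs), function(i)
    data.frame(animal_id = recs[[i]]$animal_id,
               section_id = recs[[i]]$section_id,
               layer = recs[[i]]$layer, severity = recs[[i]]$severity,
               record = i)[rep(1L, n_per[i]), , drop = FALSE]))
  rownames(meta) <- NULL
  lev <- intersect(severity_levels(), unique(meta$severity))
  list(X = X, y = factor(meta$severity, levels = lev), meta = meta,
       axis = parts[[1]]$axis)
}

## PCA ----------------------------------------------------------------------

#' Fit a PCA model retaining a target explained variance
#'
#' Mean-centred singular value decomposition (via [stats::prcomp()]);
#' the number of components is the smallest k whose cumulative explained
#' variance reaches `variance_target`, capped at `min(n - 1, p)`.
#'
#' @param X Numeric matrix, rows = samples.
#' @param variance_target Fraction in (0, 1] (default 0.95).
#' @return Object of class `pca_model`: `mean`, `loadings` (p x k),
#'   `var_fraction` (all components), `n_components`.
#' @export
pca_fit <- function(X, variance_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_samplesize("PCA needs >= 2 samples")
  if (variance_target <= 0 || variance_target > 1)
    stop_config("variance_target must be in (0, 1]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stop_degenerate("constant data: PCA undefined")
  frac <- ev / sum(ev)
  kmax <- min(nrow(X) - 1L, ncol(X))
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- kmax
  k <- min(k, kmax)
  structure(list(mean = pc$center, loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_fraction = frac, n_components = k),
            class = "pca_model")
}

#' Project data onto a fitted PCA model
#'
#' @param model A `pca_model` (fitted on training data only; test data are
#'   centred with the training mean).
#' @param X Matrix of samples to project.
#' @return Score matrix `n x n_components`.
#' @export
pca_project <- function(model, X) {
  sweep(as.matrix(X), 2L, model$mean) %*% model$loadings
}

## PLS-DA -------------------------------------------------------------------

# y coding: first level -> -1, second level -> +1.
.code_y <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop_classabsent("PLS-DA requires exactly two classes present")
  ifelse(y == levels(droplevels(y))[2L], 1, -1)
}

#' Fit a binary PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares regression of the +/-1-coded class membership on the
#' mean-centred spectra, one NIPALS component at a time with X deflation.
#' The regression vector `B` maps a centred spectrum to a continuous score;
#' the predicted class is the sign at 0. VIP scores are computed at fit time.
#'
#' @param X Matrix of preprocessed spectra (rows = samples).
#' @param y Two-class factor (second level is coded +1) or +/-1 vector.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return Object of class `plsda_model` with fields `n_lv`, `W`, `P`, `T`,
#'   `Q`, `B`, `x_mean`, `y_mean`, `levels`, `vip`, `ssy`.
#' @export
plsda_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop_config("numeric y must be coded -1/+1")
    lev <- c("neg", "pos"); yc <- as.double(y)
  } else {
    yf <- droplevels(as.factor(y)); lev <- levels(yf); yc <- .code_y(yf)
  }
  if (length(unique(yc)) < 2L) stop_classabsent("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  if (n_lv < 1L || n_lv > min(n - 1L, p))
    stop_config("n_lv must be in [1, min(n - 1, p)] = [1, %d]", min(n - 1L, p))
  x_mean <- colMeans(X); y_mean <- mean(yc)
  Xc <- sweep(X, 2L, x_mean); yr <- yc - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  Q <- numeric(n_lv); ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop_degenerate("no residual covariance at component %d", a)
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yr * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yr <- yr - t * qa
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; Q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  B <- W %*% solve(crossprod(P, W), Q)
  model <- structure(list(n_lv = n_lv, W = W, P = P, T = Tm, Q = Q,
                          B = drop(B), x_mean = x_mean, y_mean = y_mean,
                          levels = lev, ssy = ssy, vip = NULL),
                     class = "plsda_model")
  model$vip <- vip_scores(model)
  model
}

#' Continuous PLS-DA score for new spectra
#'
#' @param model A `plsda_model`.
#' @param X Matrix of spectra.
#' @param n_lv Optionally score with the first `n_lv` components only.
#' @return Numeric scores; positive predicts the second class level.
#' @export
plsda_score <- function(model, X, n_lv = model$n_lv) {
  B <- if (n_lv == model$n_lv) model$B else .pls_coef(model, n_lv)
  drop(sweep(as.matrix(X), 2L, model$x_mean) %*% B) + model$y_mean
}

.pls_coef <- function(model, a) {
  Wa <- model$W[, seq_len(a), drop = FALSE]
  Pa <- model$P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), model$Q[seq_len(a)]))
}

#' Predicted class labels from a PLS-DA model
#'
#' @inheritParams plsda_score
#' @return Factor with the model's two levels.
#' @export
plsda_predict <- function(model, X, n_lv = model$n_lv) {
  factor(model$levels[(plsda_score(model, X, n_lv) > 0) + 1L],
         levels = model$levels)
}

#' Variable importance in projection scores
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with unit-norm
#' component weights `w_a` and `SSY_a` the y-variance explained by component
#' `a`. The mean of the squared scores over the p wavenumbers is exactly 1,
#' so scores above 1 mark wavenumbers of above-average importance.
#'
#' @param model A fitted `plsda_model`.
#' @return Non-negative numeric vector, one score per wavenumber.
#' @export
vip_scores <- function(model) {
  if (sum(model$ssy) <= 0) stop_degenerate("model explains no y-variance")
  p <- nrow(model$W)
  w2 <- model$W^2 # columns already unit norm
  sqrt(p * drop(w2 %*% model$ssy) / sum(model$ssy))
}

## Venetian-blind cross-validation ------------------------------------------

# Interleaved fold assignment: samples sorted by class then id, fold of the
# i-th sorted sample = (i - 1) mod n_blinds. Keeps folds class-balanced.
venetian_folds <- function(y, n_blinds, ids = seq_along(y)) {
  ord <- order(as.integer(as.factor(y)), ids)
  folds <- integer(length(y))
  folds[ord] <- (seq_along(y) - 1L) %% n_blinds
  folds
}

#' Venetian-blind cross-validation of PLS-DA over latent-variable counts
#'
#' Folds are interleaved (every `n_blinds`-th sample after sorting by class
#' then sample id), the standard venetian-blind construction, which keeps
#' folds class-balanced. For each candidate number of latent variables the
#' misclassification rate is pooled over folds.
#'
#' @param X,y Modelling matrix and two-class labels.
#' @param max_lv Largest LV count to evaluate.
#' @param n_blinds Number of blinds/folds (default 10).
#' @param ids Optional sample ids controlling the interleave order (e.g.
#'   record numbers to approximate animal grouping).
#' @return data.frame with columns `n_lv` and `cv_error`.
#' @export
venetian_cv <- function(X, y, max_lv, n_blinds = 10, ids = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (n_blinds < 2L) stop_config("n_blinds must be >= 2")
  if (is.null(ids)) ids <- seq_along(y)
  folds <- venetian_folds(y, n_blinds, ids)
  errors <- matrix(NA_real_, n_blinds, max_lv)
  counts <- integer(n_blinds)
  for (f in seq_len(n_blinds) - 1L) {
    test <- folds == f
    if (!any(test)) next
    if (nlevels(droplevels(y[!test])) < 2L)
      stop_fold("fold %d removes an entire class; reduce n_blinds", f)
    fit <- plsda_fit(X[!test, , drop = FALSE], y[!test], max_lv)
    for (a in seq_len(max_lv)) {
      pred <- plsda_predict(fit, X[test, , drop = FALSE], a)
      errors[f + 1L, a] <- sum(pred != y[test])
    }
    counts[f + 1L] <- sum(test)
  }
  data.frame(n_lv = seq_len(max_lv),
             cv_error = colSums(errors, na.rm = TRUE) / sum(counts))
}

#' Select the number of latent variables from a CV curve
#'
#' The smallest LV count attaining the global minimum cross-validation error
#' (parsimony tie-break).
#'
#' @param cv_curve data.frame from [venetian_cv()] (or any with `n_lv`,
#'   `cv_error`).
#' @return Integer LV count.
#' @export
select_n_lv <- function(cv_curve) {
  if (nrow(cv_curve) == 0L) stop_config("empty CV curve")
  cv_curve$n_lv[which.min(cv_curve$cv_error)]
}

## Binary evaluation --------------------------------------------------------

#' Confusion-matrix evaluation of a binary classifier
#'
#' @param pred,truth Factors/vectors of predicted and true labels.
#' @param positive The positive class (disease).
#' @return Object of class `binary_eval`: `confusion` (2x2: TP, FN, FP, TN),
#'   `sensitivity`, `specificity`.
#' @export
binary_eval <- function(pred, truth, positive) {
  if (length(truth) == 0L) stop_samplesize("empty test set")
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  structure(list(
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("pos", "neg"),
                                       truth = c("pos", "neg"))),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "binary_eval")
}

#' Evaluate a PLS-DA model on a test set
#'
#' @param model A `plsda_model`.
#' @param X_test,y_test Test spectra and labels.
#' @param positive Positive (disease) class; default the model's second
#'   level.
#' @return A `binary_eval`.
#' @export
evaluate_binary <- function(model, X_test, y_test, positive = model$levels[2L]) {
  if (nrow(as.matrix(X_test)) == 0L) stop_samplesize("empty test set")
  binary_eval(plsda_predict(model, X_test), y_test, positive)
}

#' Cross-validated sensitivity and specificity of PLS-DA
#'
#' Pools the venetian-blind out-of-fold predictions at a fixed LV count into
#' one confusion matrix.
#'
#' @inheritParams venetian_cv
#' @param n_lv LV count to evaluate.
#' @param positive Positive class (default second factor level).
#' @return A `binary_eval`.
#' @export
plsda_cv_eval <- function(X, y, n_lv, n_blinds = 10, ids = NULL,
                          positive = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (is.null(positive)) positive <- levels(y)[2L]
  if (is.null(ids)) ids <- seq_along(y)
  folds <- venetian_folds(y, n_blinds, ids)
  pred <- factor(rep(levels(y)[1L], length(y)), levels = levels(y))
  for (f in seq_len(n_blinds) - 1L) {
    test <- folds == f
    if (!any(test)) next
    if (nlevels(droplevels(y[!test])) < 2L)
      stop_fold("fold %d removes an entire class; reduce n_blinds", f)
    fit <- plsda_fit(X[!test, , drop = FALSE], y[!test], n_lv)
    pred[test] <- plsda_predict(fit, X[test, , drop = FALSE])
  }
  binary_eval(pred, y, positive)
}

## VIP band follow-up -------------------------------------------------------

#' Welch tests on VIP-significant wavenumber bands
#'
#' Contiguous runs of wavenumbers with VIP above the threshold are merged
#' into bands. Runs of two or more points are compared between the two
#' classes by integrated area under the (rubber-band-corrected) spectra;
#' isolated single points by the peak absorbance intensity at that
#' wavenumber, each per record (mean over its representatives).
#'
#' @param cohort A [cohort_set()].
#' @param axis The (cropped) [wn_axis()] the VIP vector is aligned to.
#' @param vip Numeric VIP scores, one per axis point.
#' @param threshold Significance threshold (default 1).
#' @param class_a,class_b Classes compared (default control vs severe).
#' @param layer Layer to test within (default `"ALL"`).
#' @param cfg A [preprocess_config()].
#' @return data.frame (possibly empty): band high/low (cm^-1), n_points,
#'   kind (area/intensity), t_stat, p_value, mean_diff.
#' @export
vip_band_tests <- function(cohort, axis, vip, threshold = 1,
                           class_a = "control", class_b = "severe",
                           layer = "ALL", cfg = preprocess_config()) {
  v <- axis_values(axis)
  if (length(vip) != length(v)) stop_shape("vip length != axis length")
  runs <- rle(vip > threshold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  recs_a <- cohort_subset(cohort, layer, class_a)
  recs_b <- cohort_subset(cohort, layer, class_b)
  if (length(recs_a) == 0L || length(recs_b) == 0L)
    stop_classabsent("both classes must be present in layer %s", layer)
  prep_a <- lapply(recs_a, function(r)
    preprocess_record_spectra(r$spectra, cfg, "quantification"))
  prep_b <- lapply(recs_b, function(r)
    preprocess_record_spectra(r$spectra, cfg, "quantification"))
  for (i in which(runs$values)) {
    pts <- starts[i]:ends[i]
    hi <- max(v[pts]); lo <- min(v[pts])
    if (length(pts) >= 2L) {
      band <- band_definition(sprintf("vip_%g_%g", hi, lo), hi, lo)
      a <- vapply(prep_a, function(s) mean(integrate_band_set(s, band)), 0)
      b <- vapply(prep_b, function(s) mean(integrate_band_set(s, band)), 0)
      kind <- "area"
    } else {
      j <- which.min(abs(axis_values(prep_a[[1]]$axis) - v[pts]))
      a <- vapply(prep_a, function(s) mean(s$X[, j]), 0)
      b <- vapply(prep_b, function(s) mean(s$X[, j]), 0)
      kind <- "intensity"
    }
    wt <- welch_test(a, b)
    out[[length(out) + 1L]] <- data.frame(
      high = hi, low = lo, n_points = length(pts), kind = kind,
      t_stat = wt$t_stat, p_value = wt$p_value, mean_diff = wt$mean_diff)
  }
  if (length(out) == 0L)
    return(data.frame(high = double(), low = double(), n_points = integer(),
                      kind = character(), t_stat = double(),
                      p_value = double(), mean_diff = double()))
  do.call(rbind, out)
}
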
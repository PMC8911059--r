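## Multi-class severity classification: PCA reduction, four base learners
## (ANN, SVM, RF, kNN), stacked ensemble with a multinomial-logistic
## meta-learner on out-of-fold base probabilities, repeated stratified
## hold-out evaluation with per-class AUROC and classification accuracy.

#' Base classifier specification
#'
#' Declared default hyperparameters: ANN with a single hidden layer of 25
#' logistic units (sized for record-level spectral datasets of order 10^2
#' samples on a few dozen principal-component scores); SVM with radial-basis
#' kernel, cost 1, pairwise-coupled probabilities; random forest with 500
#' trees and sqrt(p) features per split; kNN with k = 5 on Euclidean
#' distance over the reduced scores. All overridable through
#' `hyperparameters`.
#'
#' @param kind One of `"ann"`, `"svm"`, `"rf"`, `"knn"`.
#' @param hyperparameters Named list overriding the defaults per kind.
#' @param seed Seed for the learner's stochastic elements.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, hyperparameters = list(), seed = 0L) {
  if (!kind %in% c("ann", "svm", "rf", "knn"))
    stop_config("unknown classifier kind '%s'", kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)), class = "classifier_spec")
}

#' Default base-learner roster
#'
#' @param seed Shared seed offset.
#' @return Named list of the four [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(seed = 0L) {
  list(ann = classifier_spec("ann", seed = seed),
       svm = classifier_spec("svm", seed = seed),
       rf  = classifier_spec("rf", seed = seed),
       knn = classifier_spec("knn", seed = seed))
}

hp <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

#' Fit one probabilistic base classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Reduced feature matrix (rows = samples).
#' @param y Factor of class labels (>= 2 classes present).
#' @return Object of class `base_classifier` exposing [predict_proba()];
#'   deterministic given the seed carried by `spec`.
#' @export
fit_base <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_classabsent("need >= 2 classes to fit a classifier")
  fit <- withr::with_seed(spec$seed, switch(
    spec$kind,
    ann = nnet::nnet(X, nnet::class.ind(y), size = hp(spec, "size", 25L),
                     softmax = TRUE, maxit = hp(spec, "maxit", 100L),
                     decay = hp(spec, "decay", 1e-4),
                     MaxNWts = 100000L, trace = FALSE),
    svm = e1071::svm(X, y, kernel = hp(spec, "kernel", "radial"),
                     cost = hp(spec, "cost", 1), probability = TRUE),
    rf = randomForest::randomForest(X, y, ntree = hp(spec, "ntree", 500L)),
    knn = caret::knn3(X, y, k = hp(spec, "k", 5L)),
    stop_config("unknown classifier kind '%s'", spec$kind)))
  structure(list(kind = spec$kind, fit = fit, levels = levels(y)),
            class = "base_classifier")
}

#' Class-probability predictions of a fitted classifier
#'
#' Rows are renormalised to sum to exactly 1 and columns follow the training
#' level order.
#'
#' @param object A `base_classifier` (or `stacked_model`).
#' @param X Feature matrix.
#' @return Matrix `n x n_classes` of probabilities.
#' @export
predict_proba <- function(object, X) UseMethod("predict_proba")

#' @export
predict_proba.base_classifier <- function(object, X) {
  X <- as.matrix(X)
  P <- switch(object$kind,
    ann = predict(object$fit, X),
    svm = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = predict(object$fit, X, type = "prob"),
    knn = predict(object$fit, X, type = "prob"))
  P <- as.matrix(P)
  if (is.null(colnames(P))) colnames(P) <- object$levels
  P <- P[, object$levels, drop = FALSE]
  P <- pmax(P, 1e-12)
  P / rowSums(P)
}

predict_class <- function(object, X) {
  P <- predict_proba(object, X)
  factor(colnames(P)[max.col(P, ties.method = "first")], levels = colnames(P))
}

## Stratified grouped folds -------------------------------------------------

# Assign each group (record) to a fold, round-robin within its class after a
# seeded shuffle, so folds are class-stratified and all rows of a group stay
# together.
grouped_stratified_folds <- function(y, groups, k, seed = 0L) {
  gi <- !duplicated(groups)
  gclass <- y[gi]; gid <- groups[gi]
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(gid))
    for (cl in unique(gclass)) {
      idx <- which(gclass == cl)
      idx <- idx[sample.int(length(idx))]
      f[idx] <- (seq_along(idx) - 1L) %% k
    }
    f
  })
  fold_of[match(groups, gid)]
}

## Stacked ensemble ---------------------------------------------------------

#' Fit a stacked ensemble classifier
#'
#' Out-of-fold class probabilities of the base learners are generated by
#' inner stratified (record-grouped) k-fold cross-validation. Per class, the
#' base kind with the best out-of-fold one-vs-rest AUROC is selected; the
#' deduplicated winners form the stack. A multinomial-logistic meta-learner
#' is fitted on the concatenated out-of-fold probabilities of the selected
#' bases, which are then refitted on the full training data.
#'
#' @param X,y Training features and labels.
#' @param specs List of [classifier_spec()] (default all four kinds).
#' @param groups Grouping vector (record ids); rows sharing a group never
#'   straddle an inner-fold boundary. Default: each row its own group.
#' @param inner_folds Inner fold count (default 5).
#' @param seed Seed for fold assignment and learner fits.
#' @return Object of class `stacked_model`: `base` (fitted selected bases),
#'   `meta` (multinomial model), `selected`, `per_class_auroc`, `levels`.
#' @export
stack_fit <- function(X, y, specs = default_classifier_specs(),
                      groups = NULL, inner_folds = 5, seed = 0L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (length(specs) < 2L) stop_config("stacking needs >= 2 base specs")
  if (is.null(groups)) groups <- seq_len(nrow(X))
  folds <- grouped_stratified_folds(y, groups, inner_folds,
                                    derive_seed(seed, "stack_folds"))
  n <- nrow(X); lev <- levels(y)
  oof <- lapply(specs, function(s) matrix(NA_real_, n, length(lev)))
  for (f in seq_len(inner_folds) - 1L) {
    test <- folds == f
    if (!any(test)) next
    if (nlevels(droplevels(y[!test])) < nlevels(y))
      stop_fold("inner fold %d removes an entire class; reduce inner_folds", f)
    for (j in seq_along(specs)) {
      sj <- specs[[j]]; sj$seed <- derive_seed(seed, "inner", j, f)
      fit <- fit_base(sj, X[!test, , drop = FALSE], y[!test])
      oof[[j]][test, ] <- predict_proba(fit, X[test, , drop = FALSE])
    }
  }
  # per-class winners on out-of-fold AUROC
  auroc_tab <- sapply(seq_along(specs), function(j)
    vapply(lev, function(cl) auroc_ovr(oof[[j]][, match(cl, lev)], y, cl), 0))
  colnames(auroc_tab) <- names(specs) %||% vapply(specs, `[[`, "", "kind")
  winners <- apply(auroc_tab, 1L, which.max)
  selected <- sort(unique(winners))
  Z <- do.call(cbind, oof[selected])
  colnames(Z) <- paste0("p_", rep(colnames(auroc_tab)[selected],
                                  each = length(lev)), "_", lev)
  meta_df <- data.frame(y = y, Z, check.names = FALSE)
  meta <- withr::with_seed(derive_seed(seed, "meta"),
    nnet::multinom(y ~ ., data = meta_df, trace = FALSE, maxit = 200))
  base <- lapply(selected, function(j) {
    sj <- specs[[j]]; sj$seed <- derive_seed(seed, "final", j)
    fit_base(sj, X, y)
  })
  structure(list(base = base, meta = meta, selected = selected,
                 per_class_auroc = auroc_tab, levels = lev,
                 meta_names = colnames(Z)),
            class = "stacked_model")
}

#' @export
predict_proba.stacked_model <- function(object, X) {
  Z <- do.call(cbind, lapply(object$base, function(b) predict_proba(b, X)))
  colnames(Z) <- object$meta_names
  P <- predict(object$meta, newdata = as.data.frame(Z), type = "probs")
  if (is.null(dim(P))) { # two-class multinom returns a vector
    P <- cbind(1 - P, P)
  }
  P <- as.matrix(P)
  colnames(P) <- object$levels
  P <- pmax(P, 1e-12)
  P / rowSums(P)
}

## AUROC --------------------------------------------------------------------

#' One-vs-rest AUROC by the rank (Mann-Whitney) formulation
#'
#' Midranks handle ties, so all-equal scores give 0.5 and the statistic is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores for membership of `class_c` (higher = more
#'   likely positive).
#' @param y_true True labels.
#' @param class_c The positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_ovr <- function(scores, y_true, class_c) {
  pos <- y_true == class_c
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_classabsent("both '%s' and rest must be present", class_c)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Repeated stratified hold-out ---------------------------------------------

#' Repeated stratified 70/30 hold-out evaluation of the stacked ensemble
#'
#' For each repeat: a stratified shuffle-split of the records (all spectra of
#' one record stay on one side), PCA reduction fitted on the training rows
#' only, stacked ensemble fitted on the reduced training rows, per-class
#' one-vs-rest AUROC and classification accuracy on the test rows. Metrics
#' are averaged over repeats.
#'
#' @param cohort A [cohort_set()].
#' @param layer Layer to classify within (`"ALL"` pools layers).
#' @param cfg A [preprocess_config()].
#' @param specs Base-learner roster (default all four kinds).
#' @param n_repeats Number of hold-out partitions (default 10).
#' @param train_frac Training fraction (default 0.7).
#' @param variance_target PCA explained-variance target (default 0.95).
#' @param inner_folds Inner stacking folds (default 5).
#' @param seed Base seed; repeat r uses seed + r - 1.
#' @return Object of class `eval_report`: `per_class` (data.frame of mean
#'   AUROC/CA per class), `auroc` and `ca` matrices (`n_repeats x classes`),
#'   `overall_ca` per repeat, `confusion` (summed over repeats).
#' @export
repeated_holdout <- function(cohort, layer = "SubMC", cfg = preprocess_config(),
                             specs = default_classifier_specs(),
                             n_repeats = 10, train_frac = 0.7,
                             variance_target = 0.95, inner_folds = 5,
                             seed = 0L) {
  cm <- cohort_matrix(cohort, layer = layer, cfg = cfg, mode = "classification")
  y <- cm$y; groups <- cm$meta$record
  lev <- levels(y)
  rec_class <- y[!duplicated(groups)]
  if (any(table(rec_class) < 2L))
    stop_samplesize("every class needs >= 2 records in layer %s", layer)
  auroc <- ca <- matrix(NA_real_, n_repeats, length(lev),
                        dimnames = list(NULL, lev))
  overall <- numeric(n_repeats)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (r in seq_len(n_repeats)) {
    rs <- derive_seed(seed, "repeat", r)
    test_rec <- withr::with_seed(rs, {
      gid <- unique(groups)
      gcl <- rec_class
      unlist(lapply(lev, function(cl) {
        idx <- gid[gcl == cl]
        n_test <- max(1L, round((1 - train_frac) * length(idx)))
        sample(idx, n_test)
      }))
    })
    test <- groups %in% test_rec
    pca <- pca_fit(cm$X[!test, , drop = FALSE], variance_target)
    Xtr <- pca_project(pca, cm$X[!test, , drop = FALSE])
    Xte <- pca_project(pca, cm$X[test, , drop = FALSE])
    model <- stack_fit(Xtr, y[!test], specs = specs,
                       groups = groups[!test], inner_folds = inner_folds,
                       seed = derive_seed(rs, "stack"))
    P <- predict_proba(model, Xte)
    pred <- factor(colnames(P)[max.col(P, ties.method = "first")], levels = lev)
    truth <- y[test]
    for (cl in lev) {
      k <- match(cl, lev)
      auroc[r, k] <- auroc_ovr(P[, k], truth, cl)
      ca[r, k] <- mean((pred == cl) == (truth == cl))
    }
    overall[r] <- mean(pred == truth)
    conf <- conf + table(factor(truth, lev), factor(pred, lev))
  }
  per_class <- data.frame(class = lev, mean_auroc = colMeans(auroc),
                          mean_ca = colMeans(ca), row.names = NULL)
  structure(list(per_class = per_class, auroc = auroc, ca = ca,
                 overall_ca = overall, confusion = conf,
                 macro_auroc = mean(auroc), macro_ca = mean(ca)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d repeats\n", nrow(x$auroc)))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("overall CA: %.3f\n", mean(x$overall_ca)))
  invisible(x)
}
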
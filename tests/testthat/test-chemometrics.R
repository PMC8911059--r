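# PCA, PLS-DA (NIPALS), venetian-blind CV, VIP scores, binary evaluation.

test_that("PCA component count tracks the intrinsic dimensionality", {
  set.seed(10)
  # data confined to a 2-D plane embedded in 6-D
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  scores <- cbind(rnorm(40, sd = 3), rnorm(40, sd = 1))
  X <- scores %*% t(basis)
  m <- pca_fit(X, 0.95)
  expect_equal(m$n_components, 2L)
  expect_equal(sum(m$var_fraction[1:2]), 1, tolerance = 1e-9)
  # reconstruction from the retained components is exact for low-rank data
  S <- pca_project(m, X)
  Xr <- S %*% t(m$loadings) + matrix(m$mean, 40, 6, byrow = TRUE)
  expect_lt(max(abs(X - Xr)), 1e-8)
  # isotropic 5-D: nearly equal eigenvalues, so 0.95 needs 4 or 5 components
  Y <- matrix(rnorm(400 * 5), 400, 5)
  expect_true(pca_fit(Y, 0.95)$n_components %in% 4:5)
  # loadings orthonormal
  G <- crossprod(pca_fit(Y, 1.0)$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # projecting the training mean gives the zero score vector (no leakage)
  expect_equal(drop(pca_project(m, matrix(m$mean, 1))), rep(0, 2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("one-LV PLS-DA recovers a single separating direction", {
  set.seed(21)
  n <- 30; p <- 8
  y <- factor(rep(c("control", "severe"), each = n / 2),
              levels = c("control", "severe"))
  X <- matrix(rnorm(n * p, sd = 0.1), n, p)
  X[, 3] <- X[, 3] + ifelse(y == "severe", 2, -2)
  m <- plsda_fit(X, y, 1)
  expect_equal(as.character(plsda_predict(m, X)), as.character(y))
  cosine <- abs(m$W[3, 1]) / sqrt(sum(m$W[, 1]^2))
  expect_gt(cosine, 0.99)
  # scores of successive components are orthogonal
  m3 <- plsda_fit(X, y, 3)
  G <- crossprod(m3$T)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[1] * diag(G)[2])
  expect_lt(max(offdiag), 1e-8)
})

test_that("full-component PLS equals the least-squares oracle", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(rnorm(60), 10, 6)  # full-rank 10 x 6 instance
    y <- rep(c(-1, 1), 5)
    m <- plsda_fit(X, y, min(nrow(X) - 1L, ncol(X)))
    ols <- stats::lm.fit(cbind(1, X), y)$coefficients[-1]
    expect_equal(unname(m$B), unname(ols), tolerance = 1e-6)
  }
})

test_that("PLS-DA on permuted labels hovers at chance in cross-validation", {
  set.seed(55)
  n <- 24; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  acc <- vapply(1:50, function(r) {
    y <- factor(sample(rep(c("a", "b"), n / 2)))
    folds <- spectroinflame:::venetian_folds(y, 4)
    correct <- 0L
    for (f in 0:3) {
      m <- plsda_fit(X[folds != f, ], y[folds != f], 1)
      correct <- correct + sum(plsda_predict(m, X[folds == f, ]) == y[folds == f])
    }
    correct / n
  }, 0)
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("venetian blinds interleave classes and score LV candidates", {
  y <- factor(rep(c("a", "b"), each = 10))
  folds <- spectroinflame:::venetian_folds(y, 5)
  # every fold receives 2 of each class
  expect_true(all(table(folds, y) == 2))
  set.seed(60)
  X <- matrix(rnorm(20 * 6, sd = 0.05), 20, 6)
  X[, 1] <- X[, 1] + ifelse(y == "b", 1, -1)
  curve <- venetian_cv(X, y, max_lv = 4, n_blinds = 5)
  expect_equal(nrow(curve), 4L)
  expect_equal(curve$cv_error, rep(0, 4))  # perfectly separable at every LV
  # a fold that would lose a whole class is refused
  y_rare <- factor(c(rep("a", 19), "b"))
  expect_error(venetian_cv(X, y_rare, max_lv = 2, n_blinds = 5),
               class = "ftir_fold_error")
})

test_that("CV error curves prefer >= 2 LVs for two-factor chemistry", {
  # signal band confounded by an overlapping interferent band: one LV mixes
  # the two, a second separates them
  v <- seq(60, 1, by = -1)
  gA <- exp(-(v - 25)^2 / 50); gB <- exp(-(v - 32)^2 / 80)
  hits <- 0L
  for (r in 1:25) {
    set.seed(700 + r)
    n <- 40
    y <- factor(rep(c("a", "b"), each = n / 2))
    conc <- ifelse(y == "b", 1.5, 1.0)
    interf <- rnorm(n, sd = 1.2)
    X <- outer(conc, gA) + outer(interf, gB) +
      matrix(rnorm(n * length(v), sd = 0.02), n)
    curve <- venetian_cv(X, y, max_lv = 5, n_blinds = 5)
    if (select_n_lv(curve) >= 2L) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * 25)
})

test_that("LV selection takes the most parsimonious global minimum", {
  expect_equal(select_n_lv(data.frame(n_lv = 1:4,
                                      cv_error = c(0.3, 0.1, 0.1, 0.2))), 2L)
  expect_equal(select_n_lv(data.frame(n_lv = 1:5,
                                      cv_error = c(0.5, 0.4, 0.3, 0.2, 0.1))), 5L)
  expect_equal(select_n_lv(data.frame(n_lv = 1:3, cv_error = rep(0.2, 3))), 1L)
})

test_that("VIP scores satisfy their algebraic identities", {
  set.seed(71)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- factor(rep(c("a", "b"), 15))
  X[, 5] <- X[, 5] + ifelse(y == "b", 1, -1)
  for (lv in 1:3) {
    m <- plsda_fit(X, y, lv)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  }
  m1 <- plsda_fit(X, y, 1)
  expect_equal(m1$vip, sqrt(12) * abs(m1$W[, 1]) / sqrt(sum(m1$W[, 1]^2)),
               tolerance = 1e-9)
})

test_that("the informative coordinate attains the maximum VIP score", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(900 + r)
    X <- matrix(rnorm(24 * 10), 24, 10)
    y <- factor(rep(c("a", "b"), 12))
    X[, 7] <- X[, 7] + ifelse(y == "b", 1.5, -1.5)
    m <- plsda_fit(X, y, 2)
    if (which.max(m$vip) == 7L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("binary evaluation reproduces hand-computed confusion rates", {
  # 32 true positives, 3 false negatives, 28 true negatives, 2 false positives
  truth <- factor(c(rep("severe", 35), rep("control", 30)),
                  levels = c("control", "severe"))
  pred <- factor(c(rep("severe", 32), rep("control", 3),
                   rep("severe", 2), rep("control", 28)),
                 levels = c("control", "severe"))
  ev <- binary_eval(pred, truth, positive = "severe")
  expect_equal(ev$confusion["pos", "pos"], 32)
  expect_equal(ev$sensitivity, 32 / 35)
  expect_equal(ev$specificity, 28 / 30)
  expect_equal(round(100 * ev$sensitivity, 1), 91.4)
  expect_equal(round(100 * ev$specificity, 1), 93.3)
  # degenerate predictions
  all_pos <- factor(rep("severe", 65), levels = c("control", "severe"))
  ev2 <- binary_eval(all_pos, truth, positive = "severe")
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 0)
  ev3 <- binary_eval(truth, truth, positive = "severe")
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$specificity, 1)
})

test_that("VIP band follow-up merges threshold runs and reports Welch stats", {
  cm <- cohort_matrix(binary_cohort, layer = "MC",
                      classes = c("control", "severe"))
  v <- axis_values(cm$axis)
  vip <- rep(0.2, length(v))
  vip[2:3] <- c(1.2, 1.3)   # a 2-point run -> integrated-area test
  vip[6] <- 1.1             # an isolated point -> peak-intensity test
  res <- vip_band_tests(binary_cohort, cm$axis, vip, layer = "MC")
  expect_equal(nrow(res), 2L)
  expect_equal(res$kind, c("area", "intensity"))
  expect_equal(res$n_points, c(2L, 1L))
  expect_equal(res$high[1], v[2])
  expect_equal(res$low[1], v[3])
  # all-below-threshold VIP vector yields an empty table, not an error
  empty <- vip_band_tests(binary_cohort, cm$axis, rep(0.5, length(v)),
                          layer = "MC")
  expect_equal(nrow(empty), 0L)
})

test_that("fitted PLS-DA separates the synthetic severe class from control", {
  cm <- cohort_matrix(binary_cohort, layer = "SubMC",
                      classes = c("control", "severe"))
  curve <- venetian_cv(cm$X, cm$y, max_lv = 6, n_blinds = 10,
                       ids = cm$meta$record)
  n_lv <- select_n_lv(curve)
  ev <- plsda_cv_eval(cm$X, cm$y, n_lv, n_blinds = 10, ids = cm$meta$record,
                      positive = "severe")
  expect_gte(ev$sensitivity, 0.9)
  expect_gte(ev$specificity, 0.9)
  # VIP-significant wavenumbers overlap the amide-I window
  m <- plsda_fit(cm$X, cm$y, n_lv)
  v <- axis_values(cm$axis)
  expect_true(any(m$vip > 1 & v >= 1600 & v <= 1700))
})
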
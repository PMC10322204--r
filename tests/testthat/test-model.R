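# PCA aggregation, stabilized lasso, the MCIDI and threshold selection.

# n x p matrix whose sample covariance (and correlation) is exactly the
# identity: scaled, centred orthogonal contrast columns.
exact_identity_matrix <- function(n = 6, p = 5) {
  h <- contr.helmert(n)                 # columns centred and orthogonal
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/") * sqrt(n - 1)
  colnames(h) <- sprintf("f%04d", seq_len(p))
  h[, seq_len(p)]
}

test_that("the identity-covariance instance retains 4 of 5 components", {
  x <- exact_identity_matrix()
  expect_equal(unname(cov(x)), diag(5), tolerance = 1e-12)
  pca <- fit_pca_80(x, target = 0.80)
  expect_equal(pca$m, 4)                # 4/5 = 0.80, inclusive rule
  expect_equal(pca$ratio, rep(0.2, 5), tolerance = 1e-9)
})

test_that("rank-1 data needs a single component", {
  set.seed(21)
  u <- rnorm(12)
  x <- u %o% c(1, -2, 0.5)
  colnames(x) <- c("a", "b", "c")
  pca <- fit_pca_80(x, scale = FALSE)
  expect_equal(pca$m, 1)
  expect_equal(pca$ratio[1], 1.0, tolerance = 1e-12)
})

test_that("retained components bracket the cumulative-variance target", {
  for (seed in 1:5) {
    coh <- small_cohort(seed = seed, n_subjects = 50, n_features = 20)
    d <- compute_difference(average_by_state(coh$utterances))
    pca <- fit_pca_80(d)
    cum <- cumsum(pca$ratio)            # independent recomputation
    expect_gte(cum[pca$m] + 1e-9, 0.80)
    if (pca$m > 1) expect_lt(cum[pca$m - 1], 0.80)
    # loadings orthonormal
    g <- crossprod(pca$rotation)
    expect_equal(unname(g), diag(ncol(pca$rotation)), tolerance = 1e-8)
    expect_true(all(diff(pca$ratio) <= 1e-12))
    expect_lte(sum(pca$ratio), 1 + 1e-12)
  }
})

test_that("zero-variance inputs are rejected", {
  x <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_pca_80(x), "zero variance|zero-variance")
  x[, 1:2] <- rnorm(20)
  expect_error(fit_pca_80(x, scale = TRUE), "c")
})

test_that("projection uses training parameters and satisfies spectral identities", {
  coh <- small_cohort(seed = 77, n_subjects = 40, n_features = 12)
  d <- compute_difference(average_by_state(coh$utterances))
  pca <- fit_pca_80(d)
  scores <- project(pca, d)
  expect_equal(unname(colMeans(scores)), rep(0, pca$m), tolerance = 1e-10)

  # a subject sitting at the training mean projects to the origin
  mean_subject <- matrix(pca$center, 1, dimnames = list(NULL, pca$features))
  expect_equal(unname(project(pca, mean_subject)), matrix(0, 1, pca$m),
               tolerance = 1e-10)

  # discarded eigenvalue mass equals the reconstruction error
  z <- scale(d[, pca$features], center = pca$center, scale = pca$scale)
  full <- project(pca, d, all_components = TRUE)
  recon <- full[, seq_len(pca$m), drop = FALSE] %*%
    t(pca$rotation[, seq_len(pca$m), drop = FALSE])
  err <- sum((z - recon)^2) / (nrow(d) - 1)
  discarded <- sum(pca$sdev[-seq_len(pca$m)]^2)
  expect_equal(err, discarded, tolerance = 1e-8)

  # feature mismatch fails loudly
  bad <- d; colnames(bad)[1] <- "not_a_feature"
  expect_error(project(pca, bad), "feature set")
})

test_that("null labels shrink coefficients to the prevalence-only model", {
  set.seed(42)
  n <- 120
  scores <- matrix(rnorm(n * 4), n, 4)
  labels <- rep(c("MCI", "healthy"), times = c(30, 90))   # independent of scores
  fit <- fit_stabilized_lasso(scores, labels, n_repeats = 5, seed = 7)
  expect_lt(max(abs(fit$alpha)), 0.15)
  expect_equal(fit$alpha0, log(30 / 90), tolerance = 0.25)
})

test_that("a perfectly predictive component dominates the averaged fit", {
  set.seed(43)
  n <- 100
  labels <- rep(c("MCI", "healthy"), each = n / 2)
  signal <- ifelse(labels == "MCI", 1.5, -1.5) + rnorm(n, sd = 0.3)
  scores <- cbind(signal, matrix(rnorm(n * 3), n, 3))
  fit <- fit_stabilized_lasso(scores, labels, n_repeats = 5, seed = 8)
  expect_gt(abs(fit$alpha[1]), 3 * max(abs(fit$alpha[-1])))
  expect_gt(fit$alpha[1], 0)             # MCI coded 1: positive slope
})

test_that("repeat averaging is seeded and reproducible", {
  set.seed(44)
  scores <- matrix(rnorm(60 * 3), 60, 3)
  labels <- sample(rep(c("MCI", "healthy"), times = c(20, 40)))
  f1 <- fit_stabilized_lasso(scores, labels, n_repeats = 1, seed = 123)
  f2 <- fit_stabilized_lasso(scores, labels, n_repeats = 1, seed = 123)
  expect_identical(f1$repeats, f2$repeats)
})

test_that("averaging over more repeats stabilizes the coefficients", {
  set.seed(45)
  n <- 90
  labels <- rep(c("MCI", "healthy"), times = c(30, 60))
  scores <- cbind(ifelse(labels == "MCI", 0.8, -0.4) + rnorm(n),
                  matrix(rnorm(n * 2), n, 2))
  # variance of the k-repeat average across independent runs, k = 1 vs 5
  avg_coef <- function(k, seed)
    fit_stabilized_lasso(scores, labels, n_repeats = k, seed = seed)$alpha[1]
  few <- vapply(1:8, function(s) avg_coef(1, 1000 + s), numeric(1))
  many <- vapply(1:8, function(s) avg_coef(5, 2000 + s), numeric(1))
  expect_lt(var(many), var(few) + 1e-12)
})

test_that("a single retained component is handled (dummy-column path)", {
  set.seed(46)
  labels <- rep(c("MCI", "healthy"), each = 30)
  scores <- matrix(ifelse(labels == "MCI", 1, -1) + rnorm(60, sd = 0.8),
                   ncol = 1)
  fit <- fit_stabilized_lasso(scores, labels, n_repeats = 3, seed = 5)
  expect_length(fit$alpha, 1)
  vals <- compute_mcidi(fit, scores)
  expect_gt(roc_auc(vals, labels)$auc, 0.8)
})

test_that("the MCIDI is the logistic of the averaged linear predictor", {
  m0 <- list(alpha0 = 0, alpha = c(0, 0))
  expect_equal(compute_mcidi(m0, c(3, -2)), 0.5)
  m1 <- list(alpha0 = log(3), alpha = numeric(0))
  expect_equal(compute_mcidi(m1, matrix(0, 1, 0)), 0.75)
  m2 <- list(alpha0 = 0, alpha = c(2, -1))
  expect_equal(compute_mcidi(m2, c(1, 1)), plogis(1))
  # limits and monotonicity in each component with the coefficient's sign
  expect_equal(compute_mcidi(m2, c(1e4, 0)), 1.0)
  grid <- seq(-3, 3, length.out = 11)
  v_up <- compute_mcidi(m2, cbind(grid, 0))
  v_dn <- compute_mcidi(m2, cbind(0, grid))
  expect_true(all(diff(v_up) > 0))
  expect_true(all(diff(v_dn) < 0))
  expect_true(all(v_up > 0 & v_up < 1))
})

test_that("balanced error rate follows its two definitions", {
  expect_equal(ber(0, 0), 0)
  expect_equal(ber(0, 0, mode = "harmonic"), 0)
  expect_equal(ber(0.2, 0.4), 0.3)
  expect_equal(ber(0.2, 0.4, mode = "harmonic"), 2 * 0.2 * 0.4 / 0.6)
  expect_equal(ber(0.3, 0, mode = "harmonic"), 0)  # the degenerate case
  expect_error(ber(1.2, 0), "fpr")
})

test_that("threshold selection is exhaustive-search optimal", {
  tau <- select_threshold(c(0.1, 0.2, 0.8, 0.9),
                          c("healthy", "healthy", "MCI", "MCI"))
  expect_equal(tau, 0.5)

  # perfectly inverted scores: no interior threshold beats the boundary
  inv <- select_threshold(c(0.9, 0.8, 0.1, 0.2),
                          c("healthy", "healthy", "MCI", "MCI"))
  o <- oracle_ber_grid(c(0.9, 0.8, 0.1, 0.2),
                       c("healthy", "healthy", "MCI", "MCI"))
  expect_equal(o$min_ber, 0.5)
  expect_true(any(abs(o$argmins - inv) < 1e-9) || inv %in% c(0, 1))

  expect_error(select_threshold(runif(5), rep("MCI", 5)), "both classes")
})

test_that("threshold search equals dense-grid minimization on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    v <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    lab <- sample(c("healthy", "MCI"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("healthy", "MCI")
    for (mode in c("arithmetic", "harmonic")) {
      tau <- select_threshold(v, lab, mode = mode)
      pos <- lab == "MCI"
      pred <- v >= tau
      achieved <- ber(mean(pred[!pos]), mean(!pred[pos]), mode = mode)
      o <- oracle_ber_grid(v, lab, mode = mode)
      expect_equal(achieved, o$min_ber, tolerance = 1e-12)
      # and tau sits within one inter-score gap of a grid argmin
      gap <- max(diff(sort(unique(c(0, v, 1)))))
      expect_lt(min(abs(o$argmins - tau)), gap + 1e-9)
    }
  }
})
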
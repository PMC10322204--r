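# PCA aggregation, stabilized L1 logistic regression, the MCIDI score and
# the BER-minimizing decision threshold.

#' PCA of selected feature differences up to a cumulative variance target
#'
#' Principal component analysis of the selected difference columns,
#' retaining the smallest number of components whose cumulative explained
#' variance ratio reaches the target (inclusive; equality is detected with
#' a 1e-9 absolute tolerance so that exact-fraction spectra land on the
#' inclusive side).  Features are centred and, by default, scaled to unit
#' variance — acoustic functionals have incommensurate units, so
#' correlation-matrix PCA is the safer default; set `scale = FALSE` for
#' covariance-matrix PCA.
#'
#' @param x Numeric matrix (subjects x selected features).
#' @param target Cumulative explained-variance target in (0, 1], default
#'   0.80.
#' @param scale Scale columns to unit variance before rotation (default
#'   `TRUE`).
#' @return Object of class `pca_model`: `center`, `scale` (or `NULL`),
#'   `rotation` (all components), `sdev`, `ratio` (explained-variance
#'   ratios), `m` (retained components), `features` (column names),
#'   `target`.
#' @export
fit_pca_80 <- function(x, target = 0.80, scale = TRUE) {
  stopifnot(is.matrix(x) || is.data.frame(x), target > 0, target <= 1)
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stopf("all features have zero variance; PCA undefined")
  if (scale && any(sds == 0))
    stopf("zero-variance feature(s) cannot be scaled: %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  m <- which(cumsum(ratio) >= target - 1e-9)[1]
  structure(list(center = pc$center,
                 scale = if (scale) pc$scale else NULL,
                 rotation = pc$rotation, sdev = pc$sdev, ratio = ratio,
                 m = m, features = colnames(x), target = target),
            class = "pca_model")
}

#' Project difference rows onto a fitted PCA basis
#'
#' Centres (and scales, if the model was fitted with scaling) new rows with
#' the *training* parameters and rotates them onto the retained components.
#' Verification cohorts are never re-fitted.
#'
#' @param pca A `pca_model` from [fit_pca_80()].
#' @param diffs Matrix or data frame with exactly the model's feature
#'   columns (any order; matched by name when named).
#' @param all_components Return scores on all components rather than the
#'   retained `m` (used for spectral identities in tests).
#' @return Numeric matrix of component scores (subjects x m).
#' @export
project <- function(pca, diffs, all_components = FALSE) {
  stopifnot(inherits(pca, "pca_model"))
  diffs <- as.matrix(diffs)
  if (!is.null(colnames(diffs))) {
    if (!setequal(colnames(diffs), pca$features))
      stopf("feature set does not match the fitted PCA")
    diffs <- diffs[, pca$features, drop = FALSE]
  } else if (ncol(diffs) != length(pca$features)) {
    stopf("expected %d feature columns, got %d", length(pca$features),
          ncol(diffs))
  }
  z <- sweep(diffs, 2, pca$center)
  if (!is.null(pca$scale)) z <- sweep(z, 2, pca$scale, "/")
  k <- if (all_components) ncol(pca$rotation) else pca$m
  z %*% pca$rotation[, seq_len(k), drop = FALSE]
}

#' Stabilized L1-regularized logistic regression
#'
#' Fits an L1-penalized (lasso) logistic regression of group on component
#' scores `n_repeats` times, choosing the penalty weight in each repeat by
#' stratified cross-validation at minimum mean binomial deviance.  The CV
#' fold assignment is random and differs across repeats — the only source
#' of run-to-run variation — so averaging the per-repeat coefficients
#' (intercept included, intercept never penalized) stabilizes the result.
#'
#' @param scores Numeric matrix (subjects x m components).
#' @param labels `"healthy"`/`"MCI"` per row; MCI is coded 1 so the model
#'   output is the probability of MCI.
#' @param n_repeats Number of repeated fits to average (default 20).
#' @param nfolds Cross-validation folds per repeat (default 5, stratified).
#' @param seed Integer seed making the repeat sequence reproducible.
#' @return List with `alpha0` (averaged intercept), `alpha` (averaged
#'   coefficients, length m), `repeats` (matrix of per-repeat coefficients,
#'   n_repeats x (m+1)), `n_repeats`, `seed`.
#' @export
fit_stabilized_lasso <- function(scores, labels, n_repeats = 20, nfolds = 5,
                                 seed = 1L) {
  scores <- as.matrix(scores)
  y <- as.integer(labels == "MCI")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  if (nrow(scores) != length(y)) stopf("scores/labels length mismatch")
  m <- ncol(scores)
  # glmnet needs >= 2 predictor columns; a constant dummy column has
  # coefficient identically 0 and is dropped afterwards.
  x <- if (m == 1) cbind(scores, `.dummy` = 0) else scores
  local_seed(seed, {
    reps <- matrix(NA_real_, n_repeats, m + 1)
    for (r in seq_len(n_repeats)) {
      foldid <- stratified_folds(y, nfolds)
      co <- tryCatch({
        # muffle glmnet's small-class caution: expected at small cohort
        # sizes and not actionable here
        cv <- withCallingHandlers(
          glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            type.measure = "deviance", foldid = foldid,
                            standardize = TRUE),
          warning = function(w) {
            if (grepl("fewer than 8", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        as.vector(stats::coef(cv, s = "lambda.min"))
      }, error = function(e) {
        warning("lasso repeat ", r, " failed (", conditionMessage(e),
                "); falling back to the largest-penalty fit", call. = FALSE)
        fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                              standardize = TRUE)
        as.vector(stats::coef(fit, s = max(fit$lambda)))
      })
      reps[r, ] <- co[seq_len(m + 1)]
    }
    avg <- colMeans(reps)
    list(alpha0 = avg[1], alpha = avg[-1], repeats = reps,
         n_repeats = n_repeats, seed = as.integer(seed))
  })
}

# Random fold labels 1..nfolds, balanced within each class.
stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' The MCI discrimination index
#'
#' The MCIDI is the logistic function of the averaged linear predictor,
#' \deqn{MCIDI = 1 / (1 + \exp(-\alpha_0 - \sum_i \alpha_i PC_i))}
#' and, with MCI coded 1, is the modelled probability that a subject
#' belongs to the MCI group.
#'
#' @param model A fitted `mcidi_model` (see [train_mcidi()]) or any list
#'   with `alpha0` and `alpha`.
#' @param scores Component-score matrix (subjects x m) or vector (one
#'   subject).
#' @return Numeric vector of MCIDI values in (0, 1).
#' @export
compute_mcidi <- function(model, scores) {
  if (is.null(dim(scores)))
    scores <- if (length(model$alpha) == 1) matrix(scores, ncol = 1)
              else matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model$alpha))
    stopf("expected %d component scores per subject, got %d",
          length(model$alpha), ncol(scores))
  as.vector(stats::plogis(model$alpha0 + scores %*% model$alpha))
}

#' Balanced error rate
#'
#' Combines the false-positive and false-negative rates symmetrically.
#' The conventional (default) form is their arithmetic mean.  A harmonic
#' variant `2ab/(a+b)` is provided for completeness but is degenerate as a
#' threshold objective: any all-one-class prediction zeroes one rate and
#' hence the harmonic mean.
#'
#' @param fpr False-positive rate in `[0, 1]`.
#' @param fnr False-negative rate in `[0, 1]`.
#' @param mode `"arithmetic"` (default) or `"harmonic"`.
#' @return The balanced error rate.
#' @export
ber <- function(fpr, fnr, mode = c("arithmetic", "harmonic")) {
  mode <- match.arg(mode)
  stopifnot(all(fpr >= 0 & fpr <= 1), all(fnr >= 0 & fnr <= 1))
  if (mode == "arithmetic") (fpr + fnr) / 2
  else ifelse(fpr + fnr == 0, 0, 2 * fpr * fnr / (fpr + fnr))
}

#' BER-minimizing decision threshold
#'
#' Scans the midpoints between consecutive sorted unique score values
#' (plus the endpoints 0 and 1) and returns the smallest candidate
#' achieving minimal balanced error rate, under the decision rule
#' "predict MCI when score >= threshold".
#'
#' @param values MCIDI (or other probability-scale) scores.
#' @param labels `"healthy"`/`"MCI"` per value.
#' @param mode BER mode, see [ber()].
#' @return The threshold in `[0, 1]`.
#' @export
select_threshold <- function(values, labels, mode = "arithmetic") {
  pos <- labels == "MCI"
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  u <- sort(unique(values))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  bers <- vapply(cand, function(tau) {
    pred <- values >= tau
    ber(mean(pred[!pos]), mean(!pred[pos]), mode = mode)
  }, numeric(1))
  cand[which.min(bers)] # which.min takes the first, i.e. smallest candidate
}
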
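# Confusion matrices, discrimination metrics, ROC/AUC, k-fold CV with the
# full pipeline refit inside each fold, Welch's t-test and the MCIDI-MMSE
# correlation.

#' Confusion matrix at a decision threshold
#'
#' Predicts MCI when the score is greater than or equal to the threshold
#' (the boundary rule is fixed so counts are deterministic).
#'
#' @param values MCIDI scores per subject.
#' @param labels `"healthy"`/`"MCI"` per subject.
#' @param tau Decision threshold in `[0, 1]`.
#' @return Object of class `mcidi_confusion`: integer vector with `tp`
#'   (MCI predicted MCI), `fn`, `fp`, `tn`.
#' @export
confusion <- function(values, labels, tau) {
  stopifnot(tau >= 0, tau <= 1, length(values) == length(labels))
  pos <- labels == "MCI"
  pred <- values >= tau
  confusion_matrix(tp = sum(pos & pred), fn = sum(pos & !pred),
                   fp = sum(!pos & pred), tn = sum(!pos & !pred))
}

#' @rdname confusion
#' @param tp,fn,fp,tn Counts, e.g. transcribed from a printed confusion
#'   table.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
              tn = as.integer(tn))
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  structure(counts, class = "mcidi_confusion")
}

#' @export
print.mcidi_confusion <- function(x, ...) {
  m <- matrix(x[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(actual = c("MCI", "healthy"),
                              predicted = c("MCI", "healthy")))
  print(m)
  invisible(x)
}

#' The six discrimination metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values, F-measure (harmonic mean of PPV and
#' sensitivity) and accuracy.  A metric with a zero denominator is
#' reported as `NA` (undefined), never silently as 0.
#'
#' @param cm An `mcidi_confusion` (from [confusion()] or
#'   [confusion_matrix()]).
#' @return Named numeric vector: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `f_measure`, `accuracy`.
#' @examples
#' classification_metrics(confusion_matrix(tp = 39, fn = 9, fp = 11, tn = 139))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "mcidi_confusion"))
  tp <- cm[["tp"]]; fn <- cm[["fn"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  acc <- div(tp + tn, tp + fn + fp + tn)
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    f_measure = f, accuracy = acc)
}

#' ROC curve and AUC
#'
#' Rank-based AUC with ties counted one half (identical to the
#' Mann-Whitney relation and to the trapezoid area under the empirical ROC
#' curve), with MCI as the positive class and no orientation flip.
#'
#' @param values Scores per subject (higher = more MCI-like).
#' @param labels `"healthy"`/`"MCI"` per subject.
#' @return List with `auc` and `curve`, a data frame of `(threshold, fpr,
#'   tpr)` points stepping through the sorted unique scores.
#' @export
roc_auc <- function(values, labels) {
  pos <- labels == "MCI"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  rk <- rank(values, ties.method = "average")
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(values[!pos] >= t) / n0, numeric(1)),
    tpr = vapply(thr, function(t) sum(values[pos] >= t) / n1, numeric(1)))
  list(auc = auc, curve = curve)
}

#' Welch's two-sample t-test of MCIDI between groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided.
#'
#' @param values MCIDI scores.
#' @param labels `"healthy"`/`"MCI"`.
#' @return List with `t`, `df`, `p`.
#' @export
group_t_test <- function(values, labels) {
  g1 <- values[labels == "MCI"]; g0 <- values[labels == "healthy"]
  if (length(g1) < 2 || length(g0) < 2)
    stopf("need at least 2 subjects per group")
  if (stats::sd(g1) == 0 && stats::sd(g0) == 0)
    stopf("degenerate (constant) values in both groups")
  ht <- stats::t.test(g1, g0, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlation between MCIDI and MMSE
#'
#' @param values MCIDI scores.
#' @param mmse MMSE scores, same subjects.
#' @return List with `r` and two-sided `p`.
#' @export
mmse_correlation <- function(values, mmse) {
  if (length(values) < 3) stopf("need at least 3 pairs")
  if (stats::sd(values) == 0 || stats::sd(mmse) == 0)
    stopf("degenerate (constant) input; correlation undefined")
  ht <- stats::cor.test(values, mmse, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Stratified k-fold cross-validation of the whole pipeline
#'
#' Splits subjects into `k` folds stratified by group (seeded).  For every
#' fold the *entire* pipeline — feature screening, PCA, stabilized lasso
#' and threshold selection — is refit on the training folds only and
#' applied to the held-out subjects, so no selection statistic ever sees
#' held-out data.  `k = n` gives leave-one-out.  If a training partition
#' lacks one of the classes the folds are re-drawn (up to `max_redraws`,
#' logged via a message).
#'
#' @param table Utterance-level feature table.
#' @param labels Label table (`subject_id`, `mmse`, `group`).
#' @param k Number of folds (`2 <= k <= n`).
#' @param config A [pipeline_config()]; its seed drives the fold draw and
#'   each fold's lasso repeats.
#' @param keep_models Keep each fold's fitted model in the result (used by
#'   leakage tests).
#' @param fit_fun Advanced: function `(table, labels, config) ->` an object
#'   with `predict_mcidi` semantics (defaults to [train_mcidi()]); lets
#'   tests substitute degenerate predictors.
#' @param max_redraws Fold re-draw limit when a training partition lacks a
#'   class.
#' @return Object of class `cv_report`: `k`, `folds` (assignment), pooled
#'   `confusion`, pooled `metrics`, `fold_metrics` (per-fold
#'   sensitivity/specificity/accuracy), `fold_means`, `predictions`, and
#'   `models` when requested.
#' @export
kfold_cv <- function(table, labels, k, config = pipeline_config(),
                     keep_models = FALSE, fit_fun = NULL,
                     max_redraws = 20) {
  n <- nrow(labels)
  stopifnot(k >= 2, k <= n)
  if (is.null(fit_fun)) fit_fun <- function(tab, lab, cfg) train_mcidi(tab, lab, cfg)
  folds <- local_seed(config$seed, {
    for (attempt in seq_len(max_redraws)) {
      if (k == n) {
        f <- sample(n)                   # leave-one-out: one subject per fold
      } else {
        f <- integer(n)
        for (g in unique(labels$group)) {
          idx <- sample(which(labels$group == g))
          f[idx] <- rep_len(sample(seq_len(k)), length(idx))
        }
      }
      ok <- all(vapply(seq_len(k), function(j)
        length(unique(labels$group[f != j])) == 2, logical(1)))
      if (ok) break
      message("fold draw ", attempt, " left a training partition ",
              "single-class; re-drawing")
      f <- NULL
    }
    if (is.null(f)) stopf("could not draw folds with two-class training sets")
    f
  })
  scores <- rep(NA_real_, n)
  pred <- logical(n)
  models <- if (keep_models) vector("list", k) else NULL
  fold_metrics <- matrix(NA_real_, k, 3,
                         dimnames = list(NULL, c("sensitivity", "specificity",
                                                 "accuracy")))
  for (j in seq_len(k)) {
    train_ids <- labels$subject_id[folds != j]
    test_ids <- labels$subject_id[folds == j]
    fit <- fit_fun(table[table$subject_id %in% train_ids, , drop = FALSE],
                   labels[folds != j, , drop = FALSE], config)
    sc <- predict_mcidi(fit, table[table$subject_id %in% test_ids, ,
                                   drop = FALSE])
    sc <- sc[test_ids]
    scores[folds == j] <- sc
    pred[folds == j] <- sc >= fit$tau
    if (keep_models) models[[j]] <- fit
    cmj <- confusion(sc, labels$group[folds == j], fit$tau)
    mj <- classification_metrics(cmj)
    fold_metrics[j, ] <- mj[c("sensitivity", "specificity", "accuracy")]
  }
  pos <- labels$group == "MCI"
  cm <- confusion_matrix(tp = sum(pos & pred), fn = sum(pos & !pred),
                         fp = sum(!pos & pred), tn = sum(!pos & !pred))
  structure(list(k = k, folds = folds, confusion = cm,
                 metrics = classification_metrics(cm),
                 fold_metrics = fold_metrics,
                 fold_means = colMeans(fold_metrics, na.rm = TRUE),
                 predictions = data.frame(subject_id = labels$subject_id,
                                          group = labels$group,
                                          mcidi = scores, predicted_mci = pred,
                                          fold = folds,
                                          stringsAsFactors = FALSE),
                 models = models),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (pooled): sensitivity %.2f, specificity %.2f, accuracy %.2f\n",
              x$k, x$metrics["sensitivity"], x$metrics["specificity"],
              x$metrics["accuracy"]))
  invisible(x)
}
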
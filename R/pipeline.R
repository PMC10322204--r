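# End-to-end training, prediction, evaluation and artifact serialization.

#' Pipeline configuration
#'
#' Collects every tunable of the derivation with its standard setting:
#' a 1% significance level for the mixed-model state screen, an
#' MMSE-correlation cutoff of 0.15, a stage-3 feature budget equal to the
#' number of training subjects, PCA up to 80% cumulative explained
#' variance, 20 averaged lasso repeats, and an arithmetic-mean balanced
#' error rate for threshold selection.  MMSE cutoffs are 28 (healthy) and
#' 24 (MCI lower bound; below that, cognitive disease, merged into MCI).
#'
#' @param alpha Stage-1 significance level.
#' @param cor_threshold Stage-2 absolute Pearson correlation cutoff
#'   (strict inequality).
#' @param n_select Stage-3 budget; `NULL` means "number of training
#'   subjects".
#' @param pca_target Cumulative explained-variance target.
#' @param pca_scale Correlation-matrix (`TRUE`, default) vs
#'   covariance-matrix PCA.
#' @param n_repeats Lasso repeats to average.
#' @param nfolds CV folds inside each lasso repeat.
#' @param ber_mode `"arithmetic"` or `"harmonic"`, see [ber()].
#' @param auc_orient Orientation-agnostic AUC ranking (see
#'   [feature_auc()]).
#' @param cv_k Default fold count for [kfold_cv()].
#' @param seed Integer seed for all stochastic steps.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.01, cor_threshold = 0.15,
                            n_select = NULL, pca_target = 0.80,
                            pca_scale = TRUE, n_repeats = 20, nfolds = 5,
                            ber_mode = "arithmetic", auc_orient = TRUE,
                            cv_k = 5, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, cor_threshold >= 0, pca_target > 0,
            pca_target <= 1, n_repeats >= 1, nfolds >= 2)
  structure(list(alpha = alpha, cor_threshold = cor_threshold,
                 n_select = n_select, pca_target = pca_target,
                 pca_scale = isTRUE(pca_scale), n_repeats = n_repeats,
                 nfolds = nfolds, ber_mode = ber_mode,
                 auc_orient = isTRUE(auc_orient), cv_k = cv_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train the MCI discrimination index
#'
#' Runs the full derivation on a training cohort: per-subject state means
#' and calculation-minus-reading differences; the three-stage feature
#' screen; PCA of the selected differences up to the cumulative-variance
#' target; stabilized L1 logistic regression on the component scores; and
#' the BER-minimizing decision threshold on the training MCIDI values.
#'
#' @param table Utterance-level feature table.
#' @param labels Label table (`subject_id`, `mmse`, `group`).
#' @param config A [pipeline_config()].
#' @return Object of class `mcidi_model`: `pca` (the [fit_pca_80()]
#'   model), `alpha0`, `alpha`, `tau`, `masks` (the `screening_masks`),
#'   `lasso` (per-repeat coefficients), `training` (per-subject MCIDI and
#'   labels), `config`, `funnel`.
#' @export
train_mcidi <- function(table, labels, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!all(c("subject_id", "mmse", "group") %in% colnames(labels)))
    stopf("labels need columns subject_id, mmse, group")
  if (length(unique(labels$group)) < 2)
    stopf("training labels must contain both groups")
  validate_utterance_table(table)
  missing <- setdiff(labels$subject_id, table$subject_id)
  if (length(missing))
    stopf("labelled subject(s) absent from the utterance table: %s",
          paste(missing, collapse = ", "))
  diffs <- compute_difference(average_by_state(table),
                              subject_order = labels$subject_id)
  n_select <- if (is.null(config$n_select)) nrow(labels) else config$n_select
  masks <- screen_features(table, labels, diffs = diffs,
                           alpha = config$alpha,
                           cor_threshold = config$cor_threshold,
                           n_select = n_select, orient = config$auc_orient)
  selected <- diffs[, masks$stage3, drop = FALSE]
  pca <- fit_pca_80(selected, target = config$pca_target,
                    scale = config$pca_scale)
  scores <- project(pca, selected)
  lasso <- fit_stabilized_lasso(scores, labels$group,
                                n_repeats = config$n_repeats,
                                nfolds = config$nfolds, seed = config$seed)
  model <- structure(list(pca = pca, alpha0 = lasso$alpha0,
                          alpha = lasso$alpha, tau = NA_real_,
                          masks = masks, lasso = lasso, config = config,
                          funnel = masks$funnel),
                     class = "mcidi_model")
  values <- compute_mcidi(model, scores)
  model$tau <- select_threshold(values, labels$group, mode = config$ber_mode)
  model$training <- data.frame(subject_id = labels$subject_id,
                               group = labels$group, mmse = labels$mmse,
                               mcidi = values, stringsAsFactors = FALSE)
  model
}

#' @export
print.mcidi_model <- function(x, ...) {
  cat("MCIDI model\n")
  cat(sprintf("  features: %d -> %d -> %d -> %d (screen funnel)\n",
              x$funnel["total"], x$funnel["stage1"], x$funnel["stage2"],
              x$funnel["stage3"]))
  cat(sprintf("  principal components retained: %d (target %.0f%%)\n",
              x$pca$m, 100 * x$pca$target))
  cat(sprintf("  non-zero averaged coefficients: %d of %d\n",
              sum(x$alpha != 0), length(x$alpha)))
  cat(sprintf("  decision threshold (min BER): %.4f\n", x$tau))
  invisible(x)
}

#' Compute MCIDI scores for a cohort
#'
#' Applies a trained model to an utterance table: state means, feature
#' differences, projection with the training PCA parameters, and the
#' logistic index.  New cohorts are never re-fitted.
#'
#' @param model A trained `mcidi_model` (or, for the default method, any
#'   object carrying a `predict` closure — an extension hook used in
#'   testing).
#' @param table Utterance-level feature table containing at least the
#'   model's selected feature columns.
#' @return Named numeric vector of MCIDI values (names = subject ids).
#' @export
predict_mcidi <- function(model, table) UseMethod("predict_mcidi")

#' @export
predict_mcidi.mcidi_model <- function(model, table) {
  diffs <- compute_difference(average_by_state(table))
  missing <- setdiff(model$pca$features, colnames(diffs))
  if (length(missing))
    stopf("table lacks selected feature column(s): %s",
          paste(missing, collapse = ", "))
  scores <- project(model$pca, diffs[, model$pca$features, drop = FALSE])
  stats::setNames(compute_mcidi(model, scores), rownames(diffs))
}

#' @export
predict_mcidi.default <- function(model, table) model$predict(table)

#' Evaluate a trained model on a cohort
#'
#' @param model A trained `mcidi_model`.
#' @param table Utterance table of the cohort to evaluate.
#' @param labels Label table of that cohort.
#' @param tag Cohort tag echoed in the report (e.g. `"training"`,
#'   `"verification"`).
#' @return List of class `mcidi_report`: `tag`, `n`, `confusion`,
#'   `metrics` (full precision), `metrics_2dp` (half-up rounding),
#'   `auc`, `roc` points, `t_test`, `mmse_cor`, `tau`.
#' @export
evaluate_cohort <- function(model, table, labels, tag = "cohort") {
  values <- predict_mcidi(model, table)[labels$subject_id]
  cm <- confusion(values, labels$group, model$tau)
  metrics <- classification_metrics(cm)
  roc <- roc_auc(values, labels$group)
  tt <- tryCatch(group_t_test(values, labels$group), error = function(e) NULL)
  mc <- tryCatch(mmse_correlation(values, labels$mmse),
                 error = function(e) NULL)
  structure(list(tag = tag, n = nrow(labels), confusion = cm,
                 metrics = metrics,
                 metrics_2dp = round_half_up(metrics, 2), auc = roc$auc,
                 roc = roc$curve, t_test = tt, mmse_cor = mc,
                 tau = model$tau, mcidi = values),
            class = "mcidi_report")
}

#' @export
print.mcidi_report <- function(x, ...) {
  cat(sprintf("Cohort '%s' (n = %d), threshold %.4f\n", x$tag, x$n, x$tau))
  print(x$confusion)
  m <- x$metrics_2dp
  cat(sprintf("sens %.2f  spec %.2f  ppv %.2f  npv %.2f  F %.2f  acc %.2f  AUC %.3f\n",
              m["sensitivity"], m["specificity"], m["ppv"], m["npv"],
              m["f_measure"], m["accuracy"], x$auc))
  if (!is.null(x$mmse_cor))
    cat(sprintf("MCIDI-MMSE correlation r = %.3f (p = %.3g)\n",
                x$mmse_cor$r, x$mmse_cor$p))
  invisible(x)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes preparation, screening, modelling and evaluation in order and,
#' when `out_dir` is given, writes `model.json`, `masks.json`,
#' `report.json` and `log.txt`, each stamped with the configuration echo,
#' its MD5 hash and the seed so a run can be reproduced exactly.
#'
#' @param table Training utterance table.
#' @param labels Training label table.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `model`, `report`, `masks` (and `paths` when files
#'   were written).
#' @export
run_full_pipeline <- function(table, labels, config = pipeline_config(),
                              out_dir = NULL) {
  model <- train_mcidi(table, labels, config)
  report <- evaluate_cohort(model, table, labels, tag = "training")
  out <- list(model = model, report = report, masks = model$masks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(model = file.path(out_dir, "model.json"),
               masks = file.path(out_dir, "masks.json"),
               report = file.path(out_dir, "report.json"),
               log = file.path(out_dir, "log.txt"))
    write_mcidi_model(model, paths[["model"]])
    write_screening_masks(model$masks, paths[["masks"]])
    hash <- config_hash(unclass(config))
    rep_json <- list(tag = report$tag, n = report$n,
                     confusion = as.list(unclass(report$confusion)),
                     metrics = as.list(report$metrics),
                     metrics_2dp = as.list(report$metrics_2dp),
                     auc = report$auc, tau = report$tau,
                     t_test = report$t_test, mmse_cor = report$mmse_cor,
                     roc = report$roc, config = unclass(config),
                     config_hash = hash, seed = config$seed)
    jsonlite::write_json(rep_json, paths[["report"]], auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    f <- model$funnel
    writeLines(c(
      sprintf("config_hash: %s", hash),
      sprintf("seed: %d", config$seed),
      sprintf("feature funnel: %d -> %d (state screen) -> %d (MMSE corr) -> %d (AUC top-n)",
              f["total"], f["stage1"], f["stage2"], f["stage3"]),
      sprintf("principal components: %d", model$pca$m),
      sprintf("threshold: %.6f", model$tau),
      sprintf("training accuracy: %.4f", report$metrics[["accuracy"]])),
      paths[["log"]])
    out$paths <- paths
  }
  out
}

#' Serialize / restore a trained model as JSON
#'
#' The JSON document carries the PCA centering means and scales, loading
#' vectors, explained-variance ratios, averaged regression coefficients,
#' the decision threshold, the configuration echo with its MD5 hash, and
#' the seed.  [read_mcidi_model()] restores a model that predicts
#' identically (to numeric precision of the decimal round-trip).
#'
#' @param model A trained `mcidi_model`.
#' @param path Output path.
#' @return Invisibly, `path` (`write`), or the restored `mcidi_model`
#'   (`read`).
#' @export
write_mcidi_model <- function(model, path) {
  stopifnot(inherits(model, "mcidi_model"))
  pca <- model$pca
  doc <- list(
    type = "mcidi_model", version = 1L,
    features = pca$features,
    center = unname(pca$center),
    scale = if (is.null(pca$scale)) NULL else unname(pca$scale),
    loadings = apply(pca$rotation[, seq_len(pca$m), drop = FALSE], 2,
                     identity, simplify = FALSE),
    ratio = pca$ratio, m = pca$m, pca_target = pca$target,
    alpha0 = model$alpha0, alpha = unname(model$alpha), tau = model$tau,
    funnel = as.list(model$funnel),
    config = unclass(model$config),
    config_hash = config_hash(unclass(model$config)),
    seed = model$config$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_mcidi_model
#' @export
read_mcidi_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "mcidi_model")) stopf("not an MCIDI model file")
  rotation <- do.call(cbind, doc$loadings)
  rownames(rotation) <- doc$features
  pca <- structure(list(center = stats::setNames(doc$center, doc$features),
                        scale = if (is.null(doc$scale)) NULL
                                else stats::setNames(doc$scale, doc$features),
                        rotation = rotation, sdev = sqrt(doc$ratio),
                        ratio = doc$ratio, m = doc$m,
                        features = doc$features, target = doc$pca_target),
                   class = "pca_model")
  cfg <- doc$config
  config <- pipeline_config(alpha = cfg$alpha,
                            cor_threshold = cfg$cor_threshold,
                            n_select = cfg$n_select,
                            pca_target = cfg$pca_target,
                            pca_scale = cfg$pca_scale,
                            n_repeats = cfg$n_repeats, nfolds = cfg$nfolds,
                            ber_mode = cfg$ber_mode,
                            auc_orient = cfg$auc_orient, cv_k = cfg$cv_k,
                            seed = cfg$seed)
  structure(list(pca = pca, alpha0 = doc$alpha0, alpha = doc$alpha,
                 tau = doc$tau, masks = NULL, lasso = NULL, config = config,
                 funnel = unlist(doc$funnel)),
            class = "mcidi_model")
}
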
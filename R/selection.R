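# Three-stage feature screen: per-feature random-intercept state-effect
# test on utterance-level rows, MMSE-correlation filter on subject-level
# differences, and descending-AUC top-n selection.

# Per-subject sufficient statistics shared by all features of a table.
# With X = [1, s] (s binary) and V_i = sigma_e^2 (I + rho J), both the GLS
# estimate and the profile deviance reduce to O(1) work per subject given
# n_i, sum(s), sum(y), sum(s*y), sum(y^2) per subject.
lmm_suffstats <- function(state, subject_id) {
  sub <- as.integer(factor(subject_id, levels = unique(subject_id)))
  s <- as.numeric(state == if (is.numeric(state)) 1 else "calculation")
  list(sub = sub, s = s, n_i = tabulate(sub), Ss = rowsum(s, sub)[, 1],
       N = length(s), n_sub = max(sub))
}

# Profile -2 log-likelihood machinery for one feature (response y).
lmm_profile <- function(y, st, rho) {
  w <- rho / (1 + st$n_i * rho)
  Sy <- rowsum(y, st$sub)[, 1]
  Sys <- rowsum(y * st$s, st$sub)[, 1]
  Syy <- sum(y * y)
  a11 <- sum(st$n_i - w * st$n_i^2)
  a12 <- sum(st$Ss - w * st$n_i * st$Ss)
  a22 <- sum(st$Ss - w * st$Ss^2)
  c1 <- sum(Sy - w * st$n_i * Sy)
  c2 <- sum(Sys - w * st$Ss * Sy)
  det <- a11 * a22 - a12^2
  b0 <- (a22 * c1 - a12 * c2) / det
  b1 <- (a11 * c2 - a12 * c1) / det
  rr <- Syy - 2 * (b0 * sum(Sy) + b1 * sum(Sys)) +
    b0^2 * st$N + 2 * b0 * b1 * sum(st$Ss) + b1^2 * sum(st$Ss)
  sr <- Sy - b0 * st$n_i - b1 * st$Ss
  Q <- rr - sum(w * sr^2)
  sig2 <- Q / st$N
  m2ll <- st$N * log(2 * pi * sig2) + sum(log1p(st$n_i * rho)) + st$N
  list(m2ll = m2ll, beta0 = b0, beta1 = b1, sig2 = sig2,
       se1 = sqrt(sig2 * a11 / det), rho = rho)
}

#' Fit the per-feature random-intercept state-effect model
#'
#' Fits, by maximum likelihood, the Gaussian linear mixed model
#' \deqn{f_{ik} = (\beta_0 + b_i) + \beta_1 s_{ik} + \epsilon_{ik}}
#' with a random intercept `b_i` per subject and `s` the calculation/reading
#' indicator, on *utterance-level* (non-averaged) rows — the repeated
#' measurements are the point of the model.  The likelihood is profiled
#' analytically down to the variance ratio `rho = var(b)/var(e)`, which is
#' optimized in one dimension; estimates match `lme4::lmer(REML = FALSE)`.
#' Inference on `beta_1` is a two-sided Wald test from the ML fit,
#' referred to a t distribution on the within-subject residual degrees of
#' freedom `N - n_subjects - 1`, so that the balanced one-row-per-state
#' design reduces to the paired t-test.
#'
#' @param values Numeric response (one acoustic feature), one entry per
#'   utterance row.
#' @param state `"calculation"`/`"reading"` labels (or a 0/1 indicator).
#' @param subject_id Subject identifier per row.
#' @return List with `beta0`, `beta1`, `se_beta1`, `p_value`,
#'   `subject_var`, `resid_var`, and `boundary` (`TRUE` when the
#'   between-subject variance is estimated at the zero boundary; the fit
#'   then falls back to that boundary estimate, with a warning).
#' @examples
#' st <- rep(c("calculation", "reading"), 10)
#' id <- rep(1:10, each = 2)
#' fit_state_lmm(rnorm(20) + (st == "calculation"), st, id)
#' @export
fit_state_lmm <- function(values, state, subject_id) {
  if (length(unique(subject_id)) < 2) stopf("need at least 2 subjects")
  s <- as.numeric(state == if (is.numeric(state)) 1 else "calculation")
  if (length(unique(s)) < 2) stopf("both states must be present")
  st <- lmm_suffstats(state, subject_id)
  res <- lmm_fit_one(values, st)
  if (res$boundary)
    warning("between-subject variance estimated at the zero boundary; ",
            "returning the boundary fit", call. = FALSE)
  res
}

lmm_fit_one <- function(y, st) {
  obj <- function(th) lmm_profile(y, st, exp(th))$m2ll
  opt <- stats::optimize(obj, interval = c(-15, 10), tol = 1e-9)
  best <- lmm_profile(y, st, exp(opt$minimum))
  at0 <- lmm_profile(y, st, 0)
  boundary <- FALSE
  if (at0$m2ll <= best$m2ll + 1e-8 || best$rho < 1e-6) {
    if (at0$m2ll <= best$m2ll + 1e-8) best <- at0
    boundary <- TRUE
  }
  z <- best$beta1 / best$se1
  # Wald test with a t reference on the within-subject residual df, so the
  # balanced one-row-per-state design reduces to the paired t-test
  df <- max(1, st$N - st$n_sub - 1)
  list(beta0 = best$beta0, beta1 = best$beta1, se_beta1 = best$se1,
       p_value = 2 * stats::pt(-abs(z), df),
       subject_var = best$rho * best$sig2, resid_var = best$sig2,
       boundary = boundary, m2ll = best$m2ll)
}

#' Stage 1: mixed-model screen over all features
#'
#' Applies [fit_state_lmm()] to every feature column of an utterance table
#' and keeps the features whose state effect is significant at `alpha`.  No
#' multiple-testing correction is applied — the screen is intentionally
#' permissive (a raw 1% level) and later stages prune further.
#'
#' @param table Utterance-level feature table (validated).
#' @param alpha Significance level for the Wald test on `beta_1`
#'   (default 0.01).
#' @return List with logical `mask`, numeric `p_values`, `beta1`, and
#'   `boundary` flags, all named by feature.  Features whose fit fails are
#'   excluded with the failure reason collected in `failures`.
#' @export
glmm_screen <- function(table, alpha = 0.01) {
  validate_utterance_table(table)
  stopifnot(alpha > 0, alpha <= 1)
  fc <- feature_cols(table)
  st <- lmm_suffstats(table$state, table$subject_id)
  p_values <- beta1 <- rep(NA_real_, length(fc))
  boundary <- rep(FALSE, length(fc))
  failures <- character(0)
  for (j in seq_along(fc)) {
    res <- tryCatch(lmm_fit_one(table[[fc[j]]], st), error = function(e) e)
    if (inherits(res, "error")) {
      failures[fc[j]] <- conditionMessage(res)
      next
    }
    p_values[j] <- res$p_value
    beta1[j] <- res$beta1
    boundary[j] <- res$boundary
  }
  names(p_values) <- names(beta1) <- names(boundary) <- fc
  mask <- !is.na(p_values) & p_values < alpha
  list(mask = mask, p_values = p_values, beta1 = beta1,
       boundary = boundary, failures = failures, alpha = alpha)
}

#' Stage 2: MMSE-correlation filter on feature differences
#'
#' Keeps features whose subject-level difference has absolute Pearson
#' correlation with the MMSE score strictly greater than `threshold`.
#' Zero-variance features have undefined correlation and are excluded.
#'
#' @param diffs Difference matrix from [compute_difference()] (subjects x
#'   features), rows aligned with `mmse`.
#' @param mmse Integer MMSE score per subject.
#' @param threshold Absolute-correlation cutoff (default 0.15, strict
#'   inequality).
#' @return List with logical `mask` and numeric `r` (NA where undefined).
#' @export
correlation_screen <- function(diffs, mmse, threshold = 0.15) {
  stopifnot(nrow(diffs) == length(mmse))
  sds <- apply(diffs, 2, stats::sd)
  r <- rep(NA_real_, ncol(diffs))
  ok <- sds > 0 & stats::sd(mmse) > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(diffs[, ok, drop = FALSE], mmse))
  names(r) <- colnames(diffs)
  mask <- !is.na(r) & abs(r) > threshold
  list(mask = mask, r = r, threshold = threshold)
}

#' Single-feature discriminability as ROC AUC
#'
#' Rank-based AUC (the probability that a random MCI subject's value
#' exceeds a random healthy subject's, ties counted one half — the
#' Mann-Whitney relation).  By default the orientation-agnostic value
#' `max(a, 1 - a)` is returned, since a feature that drops with impairment
#' is as useful as one that rises.
#'
#' @param values Per-subject numeric feature (typically a difference
#'   column).
#' @param labels `"healthy"`/`"MCI"` per subject.
#' @param orient If `TRUE` (default) return `max(a, 1 - a)`; if `FALSE`
#'   return the raw AUC with MCI as the positive class.
#' @return AUC in `[0.5, 1]` (or `[0, 1]` when `orient = FALSE`).
#' @export
feature_auc <- function(values, labels, orient = TRUE) {
  pos <- labels == "MCI"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  rk <- rank(values, ties.method = "average")
  a <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) max(a, 1 - a) else a
}

#' Stage 3: descending-AUC top-n selection
#'
#' Ranks candidate features by single-feature AUC (descending, ties broken
#' by ascending feature index for reproducibility) and keeps the top
#' `n_select`.  Capping the count at the number of training subjects keeps
#' the downstream difference covariance matrix full rank for PCA.  If fewer
#' candidates than `n_select` survive, all are kept.
#'
#' @param diffs Difference matrix (subjects x features).
#' @param labels `"healthy"`/`"MCI"` per subject (row-aligned).
#' @param n_select Number of features to keep (typically the number of
#'   training subjects).
#' @param candidates Logical mask of stage-2 survivors (default: all).
#' @param orient Passed to [feature_auc()].
#' @return List with logical `mask` and numeric `auc` (NA outside the
#'   candidate set).
#' @export
auc_rank_select <- function(diffs, labels, n_select,
                            candidates = rep(TRUE, ncol(diffs)),
                            orient = TRUE) {
  stopifnot(length(candidates) == ncol(diffs), n_select >= 1)
  auc <- rep(NA_real_, ncol(diffs))
  idx <- which(candidates)
  for (j in idx) auc[j] <- feature_auc(diffs[, j], labels, orient = orient)
  names(auc) <- colnames(diffs)
  keep <- idx[order(-auc[idx], idx)][seq_len(min(n_select, length(idx)))]
  mask <- rep(FALSE, ncol(diffs))
  mask[keep] <- TRUE
  names(mask) <- colnames(diffs)
  list(mask = mask, auc = auc)
}

#' Run the full three-stage feature screen
#'
#' Stage 1 keeps features with a significant calculation-vs-reading state
#' effect in a per-feature random-intercept mixed model fitted on
#' utterance-level rows; stage 2 keeps those whose subject-level difference
#' correlates with MMSE (|r| > threshold); stage 3 keeps the top
#' `n_select` of the survivors by single-feature AUC.  The stage masks are
#' nested by construction.
#'
#' @param table Utterance-level feature table.
#' @param labels Label table (row per subject: `subject_id`, `mmse`,
#'   `group`).
#' @param diffs Optional precomputed difference matrix with rows in
#'   `labels$subject_id` order; computed from `table` when `NULL`.
#' @param alpha Stage-1 significance level.
#' @param cor_threshold Stage-2 absolute-correlation cutoff.
#' @param n_select Stage-3 feature budget; defaults to `nrow(labels)`.
#' @param orient Orientation rule for AUC ranking (see [feature_auc()]).
#' @return Object of class `screening_masks`: stage masks `stage1`,
#'   `stage2`, `stage3`, diagnostics `p_values`, `r_mmse`, `auc`, the
#'   settings used, and the feature-count `funnel`.
#' @export
screen_features <- function(table, labels, diffs = NULL, alpha = 0.01,
                            cor_threshold = 0.15, n_select = NULL,
                            orient = TRUE) {
  if (is.null(diffs))
    diffs <- compute_difference(average_by_state(table),
                                subject_order = labels$subject_id)
  if (is.null(n_select)) n_select <- nrow(labels)
  s1 <- glmm_screen(table, alpha = alpha)
  s2 <- correlation_screen(diffs, labels$mmse, threshold = cor_threshold)
  stage2 <- s1$mask & s2$mask
  if (!any(stage2)) stopf("no features survive stages 1-2; nothing to rank")
  s3 <- auc_rank_select(diffs, labels$group, n_select, candidates = stage2,
                        orient = orient)
  structure(list(stage1 = s1$mask, stage2 = stage2, stage3 = s3$mask,
                 p_values = s1$p_values, r_mmse = s2$r, auc = s3$auc,
                 alpha = alpha, cor_threshold = cor_threshold,
                 n_select = n_select,
                 funnel = c(total = ncol(diffs), stage1 = sum(s1$mask),
                            stage2 = sum(stage2), stage3 = sum(s3$mask)),
                 failures = s1$failures),
            class = "screening_masks")
}

#' @export
print.screening_masks <- function(x, ...) {
  f <- x$funnel
  cat(sprintf(
    "Feature screen: %d -> %d (state effect, p < %g) -> %d (|r| > %g) -> %d (top AUC)\n",
    f["total"], f["stage1"], x$alpha, f["stage2"], x$cor_threshold,
    f["stage3"]))
  invisible(x)
}

#' Serialize screening masks to JSON
#'
#' @param masks A `screening_masks` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_screening_masks <- function(masks, path) {
  out <- unclass(masks)
  out$funnel <- as.list(out$funnel)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
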
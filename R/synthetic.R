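#' Configuration for the synthetic dual-task voice cohort generator
#'
#' Describes a cohort of elderly subjects recorded under two states — a
#' serial-subtraction calculation task and a reading baseline — with
#' utterance-level acoustic features that follow a random-intercept model:
#' for feature p, subject i, utterance k,
#' \deqn{f_{ikp} = \mu_p + b_{ip} + s_{ik}(\beta_{1p} + \gamma_p(30 - MMSE_i)) + \epsilon_{ikp}}
#' where `s` is 1 for calculation rows and 0 for reading rows, `b` is a
#' per-subject random intercept and `gamma_p` links the size of the state
#' effect to cognitive decline (MMSE deficit below the 30-point ceiling).
#'
#' Features come in three roles: `null` (no state effect), `state_only`
#' (a state effect, no MMSE link) and `state_mmse` (a state effect whose
#' magnitude grows with MMSE deficit — the signal the screening pipeline is
#' meant to find).
#'
#' Defaults reproduce the training-cohort conditions the pipeline was
#' designed around: 198 subjects with a 150:48 healthy:MCI split, about
#' 5.39 (SD 1.21) calculation utterances (minimum 3) and exactly 2 reading
#' utterances per subject.  `mmse_link_slope` is calibrated so planted
#' `state_mmse` features have single-feature difference AUCs in the
#' 0.63–0.70 range typical of individually weak prosody markers.
#'
#' @param n_subjects Number of subjects.
#' @param prop_mci Fraction of subjects in the MCI group (0 < prop < 1).
#' @param n_features Number of acoustic feature columns p.
#' @param frac_state_only Fraction of features with role `state_only`.
#' @param frac_state_mmse Fraction of features with role `state_mmse`.
#'   Together the two fractions must be at most 1; the remainder are nulls.
#' @param mmse_params List with elements `healthy` and `mci`, each
#'   `c(mean =, sd =)` for the group's MMSE draw (rounded, clamped).
#' @param state_effect_size Magnitude of the standardized state effect
#'   beta_1 for non-null features (sign drawn at random per feature).
#' @param mmse_link_slope Increment to the state effect per MMSE point
#'   below 30, for `state_mmse` features.
#' @param subject_sd SD of the per-subject, per-feature random intercepts.
#' @param noise_sd SD of the utterance-level residual noise.
#' @param utterance_count_params `c(mean =, sd =)` of the normal draw whose
#'   rounded value (clipped at `min_utterances`) gives each subject's
#'   calculation-utterance count.
#' @param min_utterances Minimum calculation utterances per subject.
#' @param n_reading Reading repetitions per subject (the protocol reads the
#'   number sequence twice).
#' @param strict_cutoffs If `TRUE` (default), group-conditional MMSE draws
#'   are clamped into the clinical cutoff ranges (healthy 28–30, MCI 24–27)
#'   so labels are consistent with [classify_mmse()]; if `FALSE`, draws are
#'   only clamped to the 0–30 scale.
#' @param intercept_block_cor Correlation of random intercepts within
#'   consecutive feature blocks of size `block_size` (0 = independent).
#'   Gives the PCA stage correlated structure to aggregate when wanted.
#' @param block_size Feature block size used when `intercept_block_cor > 0`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [draw_cohort()]
#' @export
synthetic_config <- function(n_subjects = 198,
                             prop_mci = 48 / 198,
                             n_features = 160,
                             frac_state_only = 0.25,
                             frac_state_mmse = 0.125,
                             mmse_params = list(healthy = c(mean = 29.6, sd = 0.6),
                                                mci = c(mean = 25.9, sd = 1.0)),
                             state_effect_size = 0.8,
                             mmse_link_slope = 0.14,
                             subject_sd = 1,
                             noise_sd = 1,
                             utterance_count_params = c(mean = 5.39, sd = 1.21),
                             min_utterances = 3,
                             n_reading = 2,
                             strict_cutoffs = TRUE,
                             intercept_block_cor = 0,
                             block_size = 8,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), prop_mci = prop_mci,
              n_features = as.integer(n_features),
              frac_state_only = frac_state_only,
              frac_state_mmse = frac_state_mmse,
              mmse_params = mmse_params,
              state_effect_size = state_effect_size,
              mmse_link_slope = mmse_link_slope,
              subject_sd = subject_sd, noise_sd = noise_sd,
              utterance_count_params = utterance_count_params,
              min_utterances = as.integer(min_utterances),
              n_reading = as.integer(n_reading),
              strict_cutoffs = isTRUE(strict_cutoffs),
              intercept_block_cor = intercept_block_cor,
              block_size = as.integer(block_size),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_subjects < 2) stopf("need at least 2 subjects")
  if (!(cfg$prop_mci > 0 && cfg$prop_mci < 1))
    stopf("prop_mci must lie strictly between 0 and 1, got %g", cfg$prop_mci)
  if (cfg$frac_state_only < 0 || cfg$frac_state_mmse < 0 ||
      cfg$frac_state_only + cfg$frac_state_mmse > 1)
    stopf("feature role fractions must be non-negative and sum to at most 1")
  for (sd_name in c("subject_sd", "noise_sd"))
    if (cfg[[sd_name]] <= 0) stopf("%s must be > 0", sd_name)
  if (cfg$utterance_count_params[["sd"]] <= 0)
    stopf("utterance count SD must be > 0")
  for (g in c("healthy", "mci"))
    if (cfg$mmse_params[[g]][["sd"]] <= 0)
      stopf("MMSE SD for group '%s' must be > 0", g)
  if (cfg$n_reading < 1) stopf("n_reading must be >= 1")
  if (cfg$min_utterances < 1) stopf("min_utterances must be >= 1")
  if (abs(cfg$intercept_block_cor) > 0.999)
    stopf("intercept_block_cor must be in (-1, 1)")
  invisible(cfg)
}

#' Draw a synthetic cohort
#'
#' Generates an utterance-level feature table, a subject label table and the
#' generating ground truth under a [synthetic_config()].  Per subject it
#' draws an MMSE score from the group-appropriate distribution, a random
#' intercept per feature, a calculation-utterance count
#' `max(min_utterances, round(Normal(mean, sd)))`, and exactly `n_reading`
#' reading rows; feature values follow the random-intercept state-effect
#' model described in [synthetic_config()].  Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param world Optional `truth` element of a previously drawn cohort.
#'   When supplied, the feature-level parameters (roles, baseline means,
#'   realized state effects and MMSE-link slopes) are reused instead of
#'   redrawn, so the new cohort consists of fresh subjects measured on the
#'   *same* features — the situation of a verification cohort from a
#'   different population.  `config$n_features` must match.
#' @return A list of class `mcidi_cohort` with elements
#'   \describe{
#'     \item{utterances}{data frame: `subject_id`, `state`
#'       (`"calculation"`/`"reading"`), `utterance_index`, feature columns
#'       `f0001`...}
#'     \item{labels}{data frame: `subject_id`, `mmse` (integer 0–30),
#'       `group` (`"healthy"`/`"MCI"`), `cd` (logical; MMSE <= 23)}
#'     \item{truth}{list: `feature_roles` (per-feature
#'       `"null"`/`"state_only"`/`"state_mmse"`), `beta1` (realized state
#'       effects), `mmse_slope` (per-feature gamma), `config`}
#'   }
#' @examples
#' coh <- draw_cohort(synthetic_config(n_subjects = 20, n_features = 8))
#' table(coh$labels$group)
#' # a verification cohort over the same features, new subjects:
#' ver <- draw_cohort(synthetic_config(n_subjects = 10, n_features = 8,
#'                                     seed = 2), world = coh$truth)
#' stopifnot(identical(ver$truth$beta1, coh$truth$beta1))
#' @export
draw_cohort <- function(config, world = NULL) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  if (!is.null(world) && length(world$feature_roles) != config$n_features)
    stopf("world has %d features but config expects %d",
          length(world$feature_roles), config$n_features)
  local_seed(config$seed, draw_cohort_impl(config, world))
}

draw_cohort_impl <- function(cfg, world = NULL) {
  n <- cfg$n_subjects
  p <- cfg$n_features
  n_mci <- max(1L, min(n - 1L, as.integer(round(n * cfg$prop_mci))))
  group <- c(rep("healthy", n - n_mci), rep("MCI", n_mci))

  mmse <- integer(n)
  for (g in c("healthy", "MCI")) {
    idx <- which(group == g)
    par <- cfg$mmse_params[[if (g == "healthy") "healthy" else "mci"]]
    draw <- round(stats::rnorm(length(idx), par[["mean"]], par[["sd"]]))
    rng <- if (!cfg$strict_cutoffs) c(0, 30)
           else if (g == "healthy") c(28, 30) else c(24, 27)
    mmse[idx] <- as.integer(pmin(rng[2], pmax(rng[1], draw)))
  }

  if (is.null(world)) {
    # feature roles and realized effects (signs random per feature)
    n_so <- as.integer(round(p * cfg$frac_state_only))
    n_sm <- as.integer(round(p * cfg$frac_state_mmse))
    roles <- rep("null", p)
    if (n_so > 0) roles[seq_len(n_so)] <- "state_only"
    if (n_sm > 0) roles[n_so + seq_len(n_sm)] <- "state_mmse"
    sign_p <- sample(c(-1, 1), p, replace = TRUE)
    beta1 <- ifelse(roles == "null", 0, sign_p * cfg$state_effect_size)
    gamma <- ifelse(roles == "state_mmse", sign_p * cfg$mmse_link_slope, 0)
    mu <- stats::rnorm(p, 0, 1)
  } else {
    roles <- world$feature_roles
    beta1 <- world$beta1
    gamma <- world$mmse_slope
    mu <- world$mu
  }

  ucp <- cfg$utterance_count_params
  n_calc <- pmax(cfg$min_utterances,
                 as.integer(round(stats::rnorm(n, ucp[["mean"]], ucp[["sd"]]))))
  rows_per_sub <- n_calc + cfg$n_reading
  total <- sum(rows_per_sub)

  subject_id <- sprintf("S%04d", rep(seq_len(n), rows_per_sub))
  state <- unlist(lapply(seq_len(n), function(i)
    c(rep("calculation", n_calc[i]), rep("reading", cfg$n_reading))),
    use.names = FALSE)
  utterance_index <- unlist(lapply(seq_len(n), function(i)
    c(seq_len(n_calc[i]), seq_len(cfg$n_reading))), use.names = FALSE)
  s <- as.numeric(state == "calculation")

  # random intercepts: n x p, optionally equicorrelated within blocks
  b <- matrix(stats::rnorm(n * p, 0, cfg$subject_sd), n, p)
  if (cfg$intercept_block_cor > 0) {
    rho <- cfg$intercept_block_cor
    blocks <- split(seq_len(p), (seq_len(p) - 1) %/% cfg$block_size)
    for (blk in blocks) {
      shared <- stats::rnorm(n, 0, cfg$subject_sd)
      b[, blk] <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(blk), 0, cfg$subject_sd),
                               n, length(blk))
    }
  }

  deficit <- 30 - mmse
  sub_idx <- rep(seq_len(n), rows_per_sub)
  # state effect per (row, feature): s * (beta1 + gamma * deficit_i)
  eff <- outer(deficit[sub_idx], gamma) + rep(1, total) %o% beta1
  values <- rep(1, total) %o% mu + b[sub_idx, , drop = FALSE] +
    s * eff + matrix(stats::rnorm(total * p, 0, cfg$noise_sd), total, p)
  colnames(values) <- sprintf("f%04d", seq_len(p))

  utterances <- data.frame(subject_id = subject_id, state = state,
                           utterance_index = utterance_index,
                           stringsAsFactors = FALSE)
  utterances <- cbind(utterances, as.data.frame(values))
  labels <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       mmse = mmse, group = group, cd = mmse <= 23,
                       stringsAsFactors = FALSE)
  truth <- list(feature_roles = roles, beta1 = beta1, mmse_slope = gamma,
                mu = mu, subject_group = group, config = unclass(cfg))
  structure(list(utterances = utterances, labels = labels, truth = truth),
            class = "mcidi_cohort")
}

#' Write a synthetic cohort to delimited text
#'
#' Writes `<prefix>_utterances.csv` (subject_id, state, utterance_index,
#' f0001...), `<prefix>_labels.csv` (subject_id, mmse, group, cd) and
#' `<prefix>_truth.json`.
#'
#' @param cohort An `mcidi_cohort` from [draw_cohort()].
#' @param prefix Path prefix for the three output files.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "mcidi_cohort"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(utterances = paste0(prefix, "_utterances.csv"),
             labels = paste0(prefix, "_labels.csv"),
             truth = paste0(prefix, "_truth.json"))
  utils::write.csv(cohort$utterances, paths[["utterances"]], row.names = FALSE)
  utils::write.csv(cohort$labels, paths[["labels"]], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
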
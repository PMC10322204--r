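# The three-stage feature screen: mixed-model state test, MMSE-correlation
# filter and AUC ranking.

test_that("the random-intercept fit matches lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(71)
  for (rep in 1:3) {
    n_sub <- 40
    counts <- pmax(3, round(rnorm(n_sub, 5.39, 1.21)))
    sub <- rep(sprintf("s%02d", seq_len(n_sub)), counts + 2)
    st <- unlist(lapply(seq_len(n_sub), function(i)
      c(rep("calculation", counts[i]), "reading", "reading")))
    y <- rnorm(length(st), sd = 0.9) +
      rep(rnorm(n_sub, sd = 1.2), counts + 2) +
      0.4 * (st == "calculation")
    mine <- fit_state_lmm(y, st, sub)
    lfit <- lme4::lmer(y ~ s + (1 | sub), REML = FALSE,
                       data = data.frame(y = y, s = as.numeric(st == "calculation"),
                                         sub = sub))
    expect_equal(mine$beta1, unname(lme4::fixef(lfit)["s"]), tolerance = 1e-6)
    expect_equal(mine$beta0, unname(lme4::fixef(lfit)["(Intercept)"]),
                 tolerance = 1e-6)
    expect_equal(mine$se_beta1,
                 unname(coef(summary(lfit))["s", "Std. Error"]),
                 tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(lfit))
    expect_equal(mine$subject_var, vc$vcov[1], tolerance = 1e-4)
    expect_equal(mine$resid_var, vc$vcov[2], tolerance = 1e-5)
  }
})

test_that("identical state distributions give a null state effect", {
  # each subject's calculation rows replicate its reading rows exactly, so
  # the within-subject state contrast is identically zero
  set.seed(5)
  n <- 15
  per_sub <- replicate(n, rnorm(2), simplify = FALSE)
  tab <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = sprintf("s%02d", i),
               state = rep(c("calculation", "reading"), each = 2),
               utterance_index = c(1:2, 1:2),
               f0001 = rep(per_sub[[i]], 2), stringsAsFactors = FALSE)))
  fit <- suppressWarnings(fit_state_lmm(tab$f0001, tab$state, tab$subject_id))
  expect_equal(fit$beta1, 0, tolerance = 1e-10)
  expect_gt(fit$p_value, 0.999)
})

test_that("balanced one-per-state designs reduce to the paired analysis", {
  set.seed(55)
  n <- 100
  for (rep in 1:5) {
    tab <- balanced_table(n, effect = 0.15)
    fit <- fit_state_lmm(tab$f0001, tab$state, tab$subject_id)
    calc <- tab$f0001[tab$state == "calculation"]
    read <- tab$f0001[tab$state == "reading"]
    expect_equal(fit$beta1, mean(calc - read), tolerance = 1e-8)
    p_paired <- t.test(calc - read)$p.value
    expect_lt(abs(fit$p_value - p_paired) / p_paired, 0.10)
  }
})

test_that("boundary (zero between-subject variance) fits warn but return", {
  # all subject means equal, so the between-subject variance component is
  # estimated at its zero boundary by construction
  n <- 30
  a <- rep(c(1, -1), length.out = n)
  tab <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 2),
                    state = rep(c("calculation", "reading"), n),
                    utterance_index = 1L,
                    f0001 = as.vector(rbind(a, -a)),
                    stringsAsFactors = FALSE)
  expect_warning(fit <- fit_state_lmm(tab$f0001, tab$state, tab$subject_id),
                 "boundary")
  expect_true(is.finite(fit$p_value))
  expect_equal(fit$subject_var, 0, tolerance = 1e-6)
})

test_that("the stage-1 screen keeps planted effects and respects alpha = 1", {
  coh <- draw_cohort(synthetic_config(n_subjects = 60, n_features = 30,
                                      frac_state_only = 0.3,
                                      frac_state_mmse = 0.1,
                                      state_effect_size = 1.0, seed = 77))
  s1 <- glmm_screen(coh$utterances, alpha = 0.01)
  planted <- coh$truth$feature_roles != "null"
  expect_true(all(s1$mask[planted]))          # power at this effect size
  expect_true(all(s1$p_values >= 0 & s1$p_values <= 1, na.rm = TRUE))

  s_all <- glmm_screen(coh$utterances, alpha = 1.0)
  expect_true(all(s_all$mask))
})

test_that("the correlation screen matches a first-principles Pearson oracle", {
  coh <- small_cohort(seed = 31, n_subjects = 40, n_features = 10)
  d <- compute_difference(average_by_state(coh$utterances),
                          subject_order = coh$labels$subject_id)
  cs <- correlation_screen(d, coh$labels$mmse, threshold = 0.15)
  for (j in 1:10)
    expect_equal(unname(cs$r[j]), oracle_pearson(d[, j], coh$labels$mmse),
                 tolerance = 1e-12)
  expect_equal(unname(cs$mask), unname(abs(cs$r) > 0.15))
})

test_that("perfectly correlated and constant features behave at the edges", {
  mmse <- c(30, 29, 28, 26, 25, 24)
  d <- cbind(perfect = -(30 - mmse), flat = rep(2, 6))
  cs <- correlation_screen(d, mmse, threshold = 0.15)
  expect_equal(unname(cs$r["perfect"]), 1)   # difference = mmse - 30
  expect_true(cs$mask[["perfect"]])
  expect_true(is.na(cs$r[["flat"]]))
  expect_false(cs$mask[["flat"]])
})

test_that("feature AUC matches brute force, the printed examples and symmetry", {
  expect_equal(feature_auc(c(1, 2, 3, 4), c("healthy", "healthy", "MCI", "MCI")),
               1.0)
  # raw pairwise count 2/4 -> 0.5
  expect_equal(feature_auc(c(3, 1, 2, 4), c("healthy", "MCI", "healthy", "MCI"),
                           orient = FALSE), 0.5)
  set.seed(88)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    v <- sample(c(rnorm(n - 2), rnorm(1), rnorm(1)))  # occasional ties below
    if (rep %% 3 == 0) v <- round(v)                  # force ties
    lab <- sample(c("healthy", "MCI"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("healthy", "MCI")
    raw <- feature_auc(v, lab, orient = FALSE)
    expect_equal(raw, oracle_auc_pairs(v, lab), tolerance = 1e-12)
    expect_equal(feature_auc(v, lab), max(raw, 1 - raw), tolerance = 1e-12)
    expect_equal(feature_auc(v, lab), feature_auc(-v, lab), tolerance = 1e-12)
  }
  expect_error(feature_auc(1:4, rep("MCI", 4)), "both classes")
})

test_that("AUC ranking keeps the top n with stable index tie-breaks", {
  set.seed(9)
  labels <- rep(c("healthy", "MCI"), times = c(12, 8))
  base <- rnorm(20)
  d <- cbind(f1 = rnorm(20),                       # noise
             f2 = (labels == "MCI") * 2 + rnorm(20, sd = 0.4),  # strong
             f3 = (labels == "MCI") * 1 + rnorm(20, sd = 0.6),  # medium
             f4 = base, f5 = base)                 # exact tie pair
  sel <- auc_rank_select(d, labels, n_select = 2)
  expect_equal(sum(sel$mask), 2)
  expect_true(sel$mask[["f2"]])

  # under-full: 3 candidates, budget 5 -> all kept
  sel2 <- auc_rank_select(d[, 1:3], labels, n_select = 5)
  expect_equal(sum(sel2$mask), 3)

  # exact tie between f4 and f5 broken by ascending index: only one slot
  sel3 <- auc_rank_select(d, labels, n_select = 1,
                          candidates = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(sel3$auc[["f4"]], sel3$auc[["f5"]])
  expect_true(sel3$mask[["f4"]])
  expect_false(sel3$mask[["f5"]])
})

test_that("planted signals occupy the top AUC ranks", {
  coh <- draw_cohort(synthetic_config(n_subjects = 150, n_features = 30,
                                      frac_state_only = 0,
                                      frac_state_mmse = 0.2,
                                      mmse_link_slope = 0.3, seed = 101))
  d <- compute_difference(average_by_state(coh$utterances),
                          subject_order = coh$labels$subject_id)
  sel <- auc_rank_select(d, coh$labels$group,
                         n_select = sum(coh$truth$feature_roles == "state_mmse"))
  planted <- coh$truth$feature_roles == "state_mmse"
  expect_gt(mean(sel$mask[planted]), 0.8)
})

test_that("the three-stage cascade is nested, deterministic and funnelled", {
  coh <- small_cohort(seed = 13, n_subjects = 70, n_features = 50)
  masks <- screen_features(coh$utterances, coh$labels)
  expect_true(all(masks$stage2 <= masks$stage1))     # stage-3 subset stage-2
  expect_true(all(masks$stage3 <= masks$stage2))
  expect_lte(sum(masks$stage3), masks$n_select)
  expect_equal(unname(masks$funnel),
               c(50, sum(masks$stage1), sum(masks$stage2), sum(masks$stage3)))
  masks2 <- screen_features(coh$utterances, coh$labels)
  expect_identical(masks$stage3, masks2$stage3)      # no randomness anywhere
  expect_identical(masks$p_values, masks2$p_values)
})

test_that("screen diagnostics serialize to JSON", {
  coh <- small_cohort(seed = 14, n_subjects = 30, n_features = 12)
  masks <- screen_features(coh$utterances, coh$labels)
  path <- tempfile(fileext = ".json")
  write_screening_masks(masks, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$funnel$total, 12)
  expect_equal(sum(doc$stage3), sum(masks$stage3))
})
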
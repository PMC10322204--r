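# Independent brute-force oracles and tiny fixture builders used across the
# test files.  These deliberately avoid the package's own computational
# paths.

# Textbook Pearson correlation, computed from first principles.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs AUC: probability a random positive exceeds a random negative,
# ties counted one half.
oracle_auc_pairs <- function(values, labels, positive = "MCI") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Exhaustive BER minimization over a dense uniform grid plus all observed
# values; returns the minimal BER and the grid points achieving it.
oracle_ber_grid <- function(values, labels, mode = "arithmetic",
                            grid_n = 1000) {
  pos <- labels == "MCI"
  grid <- sort(unique(c(seq(0, 1, length.out = grid_n), values)))
  bers <- vapply(grid, function(tau) {
    pred <- values >= tau
    fpr <- mean(pred[!pos]); fnr <- mean(!pred[pos])
    if (mode == "arithmetic") (fpr + fnr) / 2
    else if (fpr + fnr == 0) 0 else 2 * fpr * fnr / (fpr + fnr)
  }, numeric(1))
  list(min_ber = min(bers), argmins = grid[bers == min(bers)])
}

# Welch two-sample t statistic, df and two-sided p from the printed
# formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Expected value of max(min_k, round(Normal(mu, sd))): exact sum over the
# integer support.
oracle_trunc_round_mean <- function(mu, sd, min_k, upper = 60) {
  ks <- (min_k + 1):upper
  min_k * pnorm(min_k + 0.5, mu, sd) +
    sum(ks * (pnorm(ks + 0.5, mu, sd) - pnorm(ks - 0.5, mu, sd)))
}

# Hand-built utterance table: explicit rows, no generator involved.
tiny_table <- function() {
  data.frame(
    subject_id = c("a", "a", "a", "b", "b", "b", "b"),
    state = c("calculation", "calculation", "reading",
              "calculation", "reading", "reading", "reading"),
    utterance_index = c(1L, 2L, 1L, 1L, 1L, 2L, 3L),
    f0001 = c(1, 3, 2, 5, 3, 3, 3),
    f0002 = c(0, 0, 1, -2, 4, 0, 2),
    stringsAsFactors = FALSE)
}

# Balanced paired design: exactly one utterance per state per subject,
# with a known state effect.
balanced_table <- function(n_subjects, effect = 0, sd_sub = 1, sd_e = 1) {
  b <- rnorm(n_subjects, 0, sd_sub)
  data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(n_subjects)), each = 2),
    state = rep(c("calculation", "reading"), n_subjects),
    utterance_index = 1L,
    f0001 = as.vector(rbind(b + effect + rnorm(n_subjects, 0, sd_e),
                            b + rnorm(n_subjects, 0, sd_e))),
    stringsAsFactors = FALSE)
}

# Small default cohort for pipeline-level tests (fast but non-trivial).
small_cohort <- function(seed = 1, n_subjects = 80, n_features = 40) {
  draw_cohort(synthetic_config(n_subjects = n_subjects,
                               n_features = n_features, seed = seed))
}
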
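#!/usr/bin/env Rscript
# Step 1: simulate the three study cohorts.
#
# The study design records each elderly subject in two states — a serial-7s
# calculation task and a reading of the correct answers — and collects a
# training cohort in one year (198 subjects, 150 healthy / 48 MCI after
# merging the single CD case) plus two later verification cohorts from
# different populations (92 and 109 subjects).  No recordings are public,
# so we emulate the statistical structure: subject random intercepts, a
# state effect on a quarter of features, an MMSE-linked state effect on an
# eighth, and pure-noise nulls.

library(mcidi)

SEED <- 1L
out_dir <- "scratch/data"

cohorts <- list(
  training  = synthetic_config(n_subjects = 198, prop_mci = 48 / 198,
                               seed = SEED),
  verif_a   = synthetic_config(n_subjects = 92, prop_mci = 16 / 92,
                               seed = SEED + 1L),
  verif_b   = synthetic_config(n_subjects = 109, prop_mci = 19 / 109,
                               seed = SEED + 2L))

# all three cohorts measure the SAME acoustic features: the training
# cohort fixes the feature world, verification cohorts redraw subjects
world <- NULL
for (name in names(cohorts)) {
  coh <- draw_cohort(cohorts[[name]], world = world)
  if (name == "training") world <- coh$truth
  paths <- write_cohort(coh, file.path(out_dir, name))
  tal <- table(coh$labels$group)
  message(sprintf("%-9s %3d subjects (%d healthy / %d MCI), %d utterance rows -> %s",
                  name, nrow(coh$labels), tal[["healthy"]], tal[["MCI"]],
                  nrow(coh$utterances), paths[["utterances"]]))
}
message("calculation utterances per subject: mean target 5.39 (SD 1.21), min 3; ",
        "2 reading repetitions each")
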
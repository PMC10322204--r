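#!/usr/bin/env Rscript
# Step 2: per-subject state means and calculation-minus-reading feature
# differences for the training cohort, plus a cohort composition summary.

library(mcidi)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

utt <- read_utterance_table("scratch/data/training_utterances.csv")
lab <- read_label_table("scratch/data/training_labels.csv")

means <- average_by_state(utt)
diffs <- compute_difference(means, subject_order = lab$subject_id)

summary_tab <- do.call(rbind, lapply(split(lab, lab$group), function(g)
  data.frame(group = g$group[1], n = nrow(g),
             mmse_mean = round(mean(g$mmse), 2),
             mmse_sd = round(sd(g$mmse), 2),
             n_cd_merged = sum(g$cd))))
write.csv(summary_tab, "results/tables/cohort_summary.csv", row.names = FALSE)
print(summary_tab, row.names = FALSE)

calc_counts <- means$n_utterances[means$state == "calculation"]
message(sprintf("calculation utterances: mean %.2f (SD %.2f), range %d-%d",
                mean(calc_counts), sd(calc_counts), min(calc_counts),
                max(calc_counts)))
message(sprintf("difference matrix: %d subjects x %d features",
                nrow(diffs), ncol(diffs)))
write.csv(data.frame(subject_id = rownames(diffs), diffs),
          "scratch/training_differences.csv", row.names = FALSE)
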
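#!/usr/bin/env Rscript
# Activity mapping: percent pS6+ of DAPI per subject from the region count
# tables of 01_simulate.R, the control-vs-knockout comparison under the
# normality-gated policy, and the headline percent reduction.

suppressMessages(library(vnoca))

dir.create("results", showWarnings = FALSE)
ps6 <- read_count_table("results/data/ps6_counts.csv")

per_subj <- percent_positive(ps6, per_subject = TRUE)
per_subj$group <- ifelse(grepl("^ctrl", per_subj$subject_id), "control",
                         "knockout")
utils::write.csv(per_subj, "results/ps6_per_subject.csv", row.names = FALSE)

mc <- mean(per_subj$percent_positive[per_subj$group == "control"])
mk <- mean(per_subj$percent_positive[per_subj$group == "knockout"])
red <- percent_reduction(mc, mk)
cat(sprintf("pS6+ of DAPI: control %.2f%%, knockout %.2f%% -> %d%% reduction\n",
            mc, mk, red))
tst <- compare_two_groups(
  per_subj$percent_positive[per_subj$group == "control"],
  per_subj$percent_positive[per_subj$group == "knockout"])
print(tst)

# c-Fos-style per-area densities for the same regions, per subject
dens <- density_per_area(ps6, per_subject = TRUE)
utils::write.csv(dens, "results/cfos_density_per_subject.csv",
                 row.names = FALSE)
cat(sprintf("positive-cell density: %.2g cells/um^2 (grand mean)\n",
            mean(dens$density_per_um2)))
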
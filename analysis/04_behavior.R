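#!/usr/bin/env Rscript
# Behavioral preference: reads the bout logs from 01_simulate.R, computes
# per-animal log2 investigation-time ratios (side A = the healthy-condition
# stimulus), the group mean with its one-sample test against zero, and the
# between-genotype comparison of scores.

suppressMessages(library(vnoca))

dir.create("results", showWarnings = FALSE)
ctrl <- read_bouts("results/data/bouts_control.csv")
ko <- read_bouts("results/data/bouts_knockout.csv")

sc_ctrl <- score_sessions(ctrl)
sc_ko <- score_sessions(ko)
utils::write.csv(rbind(cbind(group = "control", sc_ctrl),
                       cbind(group = "knockout", sc_ko)),
                 "results/preference_scores.csv", row.names = FALSE)

g_ctrl <- group_preference(sc_ctrl$score)
g_ko <- group_preference(sc_ko$score)
cat("control ");  print(g_ctrl)
cat("knockout "); print(g_ko)
cat(sprintf("control mean IT: A %.1f s, B %.1f s (score of means %.2f; the\n",
            mean(sc_ctrl$it_a), mean(sc_ctrl$it_b),
            preference_score(mean(sc_ctrl$it_a), mean(sc_ctrl$it_b))))
cat("group statistic above is the mean of per-animal scores, as reported)\n")

between <- compare_two_groups(sc_ctrl$score, sc_ko$score)
cat("control vs knockout scores: "); print(between)
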
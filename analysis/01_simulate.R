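#!/usr/bin/env Rscript
# Generates the synthetic inputs every later stage consumes: a demo imaging
# site (trace table + protocol + ground truth), an image stack for knob
# detection, behavior bout logs, and activity-count tables. Everything is
# seeded; re-running reproduces the files bit for bit.

suppressMessages(library(vnoca))

seed <- 20260927L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

protocol <- default_protocol(stimuli = c("PBS", "LPS"))
write_protocol(protocol, "results/data/protocol.yaml")

# one modest demo site (~530 knobs, 80 x 80 um) kept small enough to ship
# as a readable CSV; the full-scale runs in 03_imaging.R regenerate their
# data in memory instead
cfg <- synth_config(seed = seed, field_area = c(80, 80))
field <- generate_knob_field(cfg)
ds <- generate_trace_dataset(field, protocol, cfg)
write_trace_table(ds$traces, "results/data/demo_site_traces.csv",
                  site_id = "demo1")
utils::write.csv(ds$truth$classes, "results/data/demo_site_truth.csv",
                 row.names = FALSE)
utils::write.csv(field, "results/data/demo_site_knobs.csv",
                 row.names = FALSE)
cat(sprintf("demo imaging site: %d knobs, %d frames, planted classes: %s\n",
            nrow(ds$traces), ncol(ds$traces),
            paste(names(table(ds$truth$classes$class)),
                  table(ds$truth$classes$class), collapse = ", ")))

# a still image of a 60 x 60 um field for the knob-detection stage
cfg_img <- synth_config(seed = seed + 1L, field_area = c(60, 60))
field_img <- generate_knob_field(cfg_img)
stack <- render_stack(field_img, matrix(1000, nrow(field_img), 1),
                      psf_sigma_um = 0.6, pixel_um = 0.25, background = 5)
write_stack_tiff(stack, "results/data/knob_field.tif")
utils::write.csv(field_img, "results/data/knob_field_truth.csv",
                 row.names = FALSE)
cat(sprintf("knob-detection field: %d knobs rendered to %s\n",
            nrow(field_img), "results/data/knob_field.tif"))

# behavior: a control-like cohort planted at the published group score and
# a knockout-like cohort with reversed preference
b6 <- generate_behavior_cohort(11, planted_mu = 0.81, seed = seed + 2L)
ko <- generate_behavior_cohort(14, planted_mu = -0.47, seed = seed + 3L)
ko$subject_id <- sub("^m", "ko", ko$subject_id)
utils::write.csv(b6, "results/data/bouts_control.csv", row.names = FALSE)
utils::write.csv(ko, "results/data/bouts_knockout.csv", row.names = FALSE)
cat(sprintf("behavior: %d control and %d knockout sessions written\n",
            length(unique(b6$subject_id)), length(unique(ko$subject_id))))

# activity counts: pS6 fractions per genotype (per-subject region tables)
set.seed(seed + 4L)
ps6 <- do.call(rbind, c(
  lapply(1:6, function(i)
    generate_count_regions(sample(6:15, 1), p_positive = 0.0219,
                           subject_id = sprintf("ctrl%02d", i),
                           seed = seed + 10L + i)),
  lapply(1:5, function(i)
    generate_count_regions(sample(6:15, 1), p_positive = 0.0098,
                           subject_id = sprintf("ko%02d", i),
                           seed = seed + 30L + i))))
utils::write.csv(ps6, "results/data/ps6_counts.csv", row.names = FALSE)
cat(sprintf("counts: %d pS6 regions over %d subjects written\n",
            nrow(ps6), length(unique(ps6$subject_id))))
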
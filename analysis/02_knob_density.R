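#!/usr/bin/env Rscript
# Knob detection and density estimation: detects knob-like spots in the
# rendered field from 01_simulate.R, scores recall/precision against the
# generator's truth table, estimates density from 40 x 40 um sampling
# squares, and derives the pooled density constant and total-knob numbers.

suppressMessages(library(vnoca))

dir.create("results", showWarnings = FALSE)
img <- read_stack_tiff("results/data/knob_field.tif")[, , 1]
truth <- utils::read.csv("results/data/knob_field_truth.csv")

det <- detect_knobs(img, pixel_um = 0.25)
dmat <- outer(truth$x_um, det$x_um, "-")^2 +
  outer(truth$y_um, det$y_um, "-")^2
recall <- mean(apply(dmat, 1, min) <= 1)
precision <- mean(apply(dmat, 2, min) <= 1)
cat(sprintf("detected %d of %d knobs: recall %.3f, precision %.3f (1-um match)\n",
            nrow(det), nrow(truth), recall, precision))
utils::write.csv(det, "results/knob_detections.csv", row.names = FALSE)

# density from randomly placed 40 x 40 um sampling squares
set.seed(20260927)
n_sq <- 13
sq <- data.frame(x0 = runif(n_sq, 0, 20), y0 = runif(n_sq, 0, 20))
counts <- mapply(function(x0, y0)
  sum(det$x_um >= x0 & det$x_um < x0 + 40 &
        det$y_um >= y0 & det$y_um < y0 + 40), sq$x0, sq$y0)
est <- estimate_density(counts)
cat(sprintf("density from %d squares: %.2f +/- %.2f knobs/100 um^2 (truth 8.32)\n",
            est$n_squares, est$density, est$sem))

# pooling the two genotype means reproduces the working constant, which
# converts recorded areas to total knob numbers
pool <- pooled_density(c(8.42, 8.21))
cat(sprintf("pooled genotype density: %.2f knobs/100 um^2\n", pool))
cat(sprintf("total knobs: %d in 40,000 um^2, %d in 13,000 um^2\n",
            estimate_total_knobs(40000, pool),
            estimate_total_knobs(13000, pool)))
utils::write.csv(
  data.frame(quantity = c("recall", "precision", "density_mean",
                          "density_sem", "pooled_density"),
             value = c(recall, precision, est$density, est$sem, pool)),
  "results/knob_density.csv", row.names = FALSE)
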
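test_that("knob fields have the requested density, spacing and determinism", {
  cfg <- synth_config(seed = 11, field_area = c(100, 100))
  f <- generate_knob_field(cfg)
  expect_equal(attr(f, "area_um2"), 1e4)
  # expected count = density * area / 100 = 832; lattice placement is nearly
  # deterministic, allow generous boundary slack
  expect_gt(nrow(f), 832 * 0.93)
  expect_lt(nrow(f), 832 * 1.07)
  # physical non-overlap: no two knobs within 2 um
  d <- dist(cbind(f$x_um, f$y_um))
  expect_gte(min(d), 2)
  expect_true(all(f$x_um >= 0 & f$x_um < 100 & f$y_um >= 0 & f$y_um < 100))

  f2 <- generate_knob_field(cfg)
  expect_identical(f, f2)

  empty <- generate_knob_field(synth_config(seed = 1, knob_density = 0,
                                            field_area = c(50, 50)))
  expect_equal(nrow(empty), 0)
  expect_error(generate_knob_field(synth_config(seed = 1,
                                                field_area = c(-1, 10))),
               "positive")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(class_fractions = c(A_only = 0.6, B_only = 0.5,
                                                both = 0.2)), "sum")
  expect_error(synth_config(amp_range = c(1.5, 3)), "exceed 2")
  expect_error(synth_config(respond_prob = 0), "respond_prob")
  expect_error(synth_config(noise_sd = 0), "amp_ref_sd")
  expect_silent(synth_config(noise_sd = 0, amp_ref_sd = 0.02))
})

test_that("planted class counts follow the multinomial fractions", {
  cfg <- synth_config(seed = 5, field_area = c(155, 155))  # ~2000 knobs
  p <- default_protocol()
  ds <- generate_trace_dataset(generate_knob_field(cfg), p, cfg)
  tab <- table(ds$truth$classes$class)
  n <- nrow(ds$truth$classes)
  expect_equal(sum(tab), n)   # every knob exactly one class
  # expectations ~ (32, 10, 2) per 2000 knobs; check within 3 binomial SE
  for (cl in c("both", "A_only", "B_only")) {
    p0 <- cfg$class_fractions[[cl]]
    expect_lt(abs(tab[[cl]] - n * p0), 3 * sqrt(n * p0 * (1 - p0)) + 1)
  }
  # fire events only for stimuli in the knob's class
  ev <- merge(ds$truth$events, ds$truth$classes, by = "knob_id")
  ok <- (ev$class == "both") |
    (ev$class == "A_only" & ev$stimulus == "A") |
    (ev$class == "B_only" & ev$stimulus == "B")
  expect_true(all(ok))
})

test_that("trace generation is linear in F0 and reproducible", {
  p <- default_protocol()
  cfg1 <- synth_config(seed = 9, field_area = c(40, 40))
  f <- generate_knob_field(cfg1)
  ds1 <- generate_trace_dataset(f, p, cfg1)
  cfg2 <- synth_config(seed = 9, field_area = c(40, 40),
                       f0_range = cfg1$f0_range * 2)
  ds2 <- generate_trace_dataset(f, p, cfg2)
  expect_equal(ds2$traces, 2 * ds1$traces, tolerance = 1e-12)
  n1 <- normalize_traces(ds1$traces, p)
  n2 <- normalize_traces(ds2$traces, p)
  expect_equal(unclass(n1), unclass(n2), tolerance = 1e-12,
               ignore_attr = TRUE)
  ds3 <- generate_trace_dataset(f, p, cfg1)
  expect_identical(ds1$traces, ds3$traces)
})

test_that("noiseless planted responders are recovered perfectly", {
  p <- default_protocol()
  cfg <- synth_config(seed = 4, field_area = c(80, 80), noise_sd = 0,
                      amp_ref_sd = 0.02, amp_range = c(6, 6),
                      respond_prob = 1)
  f <- generate_knob_field(cfg)
  ds <- generate_trace_dataset(f, p, cfg)
  an <- analyze_site(ds)
  m <- merge(ds$truth$classes, an$profiles[c("knob_id", "class")],
             by = "knob_id")
  expect_true(all(as.character(m$class.x) == as.character(m$class.y)))
  expect_gt(sum(m$class.x != "none"), 0)  # the field did plant responders
})

test_that("lowering respond_prob breaks the repeatability criterion", {
  p <- default_protocol()
  cfg <- synth_config(seed = 21, field_area = c(200, 200),
                      class_fractions = c(A_only = 0.2, B_only = 0,
                                          both = 0),
                      respond_prob = 0.5)
  ds <- generate_trace_dataset(generate_knob_field(cfg), p, cfg)
  an <- analyze_site(ds)
  truthA <- ds$truth$classes$knob_id[ds$truth$classes$class == "A_only"]
  called <- an$profiles$knob_id[an$profiles$responds_A]
  # with fire probability 0.5 per application, only ~25% of planted
  # responders satisfy "respond on both applications"
  frac <- length(intersect(called, truthA)) / length(truthA)
  expect_lt(frac, 0.4)
  expect_gt(frac, 0.1)
})

test_that("behavior cohorts carry the planted preference", {
  null <- score_sessions(generate_behavior_cohort(40, planted_mu = 0,
                                                  seed = 2))
  expect_lt(abs(mean(null$score)), 3 * sd(null$score) / sqrt(40))
  coh <- score_sessions(generate_behavior_cohort(40, planted_mu = 0.8,
                                                 seed = 3))
  expect_gt(mean(coh$score), 0.4)
  # investigation totals match generator expectation (rate 10, mean 3 s)
  expect_lt(abs(mean(coh$it_b) - 30), 3 * sd(coh$it_b) / sqrt(40))
  expect_lt(abs(mean(coh$it_a) - 30 * 2^0.8),
            3 * sd(coh$it_a) / sqrt(40))
  # relabelling sides negates every score exactly
  b <- generate_behavior_cohort(5, planted_mu = 0.8, seed = 4)
  sw <- b; sw$label <- ifelse(b$label == "A", "B", "A")
  expect_equal(score_sessions(sw)$score, -score_sessions(b)$score)
  # bouts are inside the session and non-overlapping per subject
  expect_true(all(b$stop_s <= attr(b, "session_length_s")))
  for (s in unique(b$subject_id)) {
    x <- b[b$subject_id == s, ]
    x <- x[order(x$start_s), ]
    expect_true(all(x$start_s[-1] >= x$stop_s[-nrow(x)]))
  }
})

test_that("count-region generator matches its binomial model", {
  z <- generate_count_regions(10, p_positive = 0, seed = 1)
  expect_true(all(z$positive_count == 0))
  expect_identical(generate_count_regions(8, seed = 7),
                   generate_count_regions(8, seed = 7))
  ctrl <- generate_count_regions(400, p_positive = 0.0219, seed = 8)
  ko <- generate_count_regions(400, p_positive = 0.0098, seed = 9)
  red <- percent_reduction(mean(percent_positive(ctrl)),
                           mean(percent_positive(ko)), digits = 1)
  expect_lt(abs(red - 55.25), 3)
  expect_error(generate_count_regions(5, p_positive = 1.2), "p_positive")
})
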
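toy_protocol <- function() {
  # 50 frames total: 10 baseline frames, one stimulus twice, short latency
  stim_protocol(data.frame(stimulus = c("A", "A"),
                           onset_frame = c(12L, 30L), duration_s = 6),
                baseline_frames = c(0L, 10L), latency_window_s = 15,
                min_isi_s = 0, n_frames = 50L)
}

test_that("normalization divides by baseline mean and is scale invariant", {
  p <- default_protocol()
  const <- rep(500, p$n_frames)
  expect_equal(unname(as.vector(normalize_traces(const, p))),
               rep(1, p$n_frames))
  tr <- matrix(runif(2 * p$n_frames, 400, 600), 2,
               dimnames = list(c("a", "b"), NULL))
  n1 <- normalize_traces(tr, p)
  n3 <- normalize_traces(3 * tr, p)
  expect_equal(n1, n3, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowMeans(n1[, 1:50])), c(1, 1))
})

test_that("a planted 20% transient normalizes to a peak near 1.2", {
  p <- default_protocol()
  cfg <- synth_config(seed = 2, noise_sd = 0, amp_ref_sd = 0.02,
                      amp_range = c(10, 10),  # 10 x 2% = 20% of F0
                      class_fractions = c(A_only = 1, B_only = 0, both = 0),
                      latency_range_s = c(3, 3))
  field <- data.frame(knob_id = "k1", x_um = 1, y_um = 1)
  ds <- generate_trace_dataset(field, p, cfg)
  norm <- normalize_traces(ds$traces, p)
  # frame grid does not land exactly on the kernel peak; 1.5% slack
  expect_equal(max(norm), 1.2, tolerance = 0.015)
})

test_that("normalization rejects bad baselines by knob id", {
  p <- toy_protocol()
  tr <- matrix(1, 2, 50, dimnames = list(c("good", "bad"), NULL))
  tr["bad", 1:10] <- 0
  expect_error(normalize_traces(tr, p), "bad")
  tr2 <- matrix(1, 1, 5)
  expect_error(normalize_traces(tr2, p), "baseline")
  tr3 <- matrix(c(rep(1, 49), NA), 1, 50)
  expect_error(normalize_traces(tr3, p), "non-finite")
})

test_that("baseline statistics are the sample mean and SD of the window", {
  p <- toy_protocol()
  ones <- rep(1, 50)
  bs <- baseline_stats(ones, p)
  expect_equal(bs$mean_b, 1)
  expect_equal(bs$sd_b, 0)
  alt <- rep(c(0.99, 1.01), 25)
  bs2 <- baseline_stats(alt, p)   # 10-frame window of alternating values
  expect_equal(bs2$mean_b, 1)
  expect_equal(bs2$sd_b, 0.01 * sqrt(10 / 9), tolerance = 1e-12)
  # Gaussian noise: SD estimate within its own sampling error
  p50 <- default_protocol()
  set.seed(1)
  z <- 1 + rnorm(p50$n_frames, 0, 0.02)
  bs3 <- baseline_stats(normalize_traces(z * 800, p50), p50)
  expect_lt(abs(bs3$sd_b - 0.02), 3 * 0.02 / sqrt(2 * (50 - 1)))
})

test_that("responses obey threshold, latency window and sustained-run rule", {
  p <- toy_protocol()
  base <- rep(1, 50)
  bs <- data.frame(mean_b = 1, sd_b = 0.01)

  # sub-threshold trace never responds
  flat <- base + 0.015
  calls <- detect_responses(rbind(flat), bs, p, min_run_frames = 1L)
  expect_true(!any(calls$responded))

  # sustained step 3 frames after onset: responds, latency 4.5 s
  step <- base; step[(12 + 3 + 1):50] <- 1.05
  calls <- detect_responses(rbind(step), bs, p, min_run_frames = 3L)
  first <- calls[calls$application_index == 1, ]
  expect_true(first$responded)
  expect_equal(first$latency_s, 4.5)
  expect_equal(first$first_crossing_frame, 15)
  expect_gte(first$peak_amplitude, 1 + 2 * 0.01)

  # excursion beginning after the latency window does not count
  late <- base; late[(12 + 11 + 1):50] <- 1.05   # 16.5 s > 15 s window
  calls <- detect_responses(rbind(late), bs, p, min_run_frames = 1L)
  expect_false(calls$responded[calls$application_index == 1][1])

  # single-frame spike is rejected by the sustained-run criterion but
  # accepted under the literal first-crossing rule
  spike <- base; spike[12 + 2] <- 1.08
  r3 <- detect_responses(rbind(spike), bs, p, min_run_frames = 3L)
  r1 <- detect_responses(rbind(spike), bs, p, min_run_frames = 1L)
  expect_false(r3$responded[1])
  expect_true(r1$responded[1])

  # application window beyond the trace is a data error
  short <- stim_protocol(data.frame(stimulus = c("A", "A"),
                                    onset_frame = c(12L, 45L)),
                         baseline_frames = c(0L, 10L), latency_window_s = 15,
                         min_isi_s = 0, n_frames = 56L)
  expect_error(detect_responses(rbind(base), bs, short), "exceeds")
})

test_that("vectorized detection agrees exactly with the exhaustive oracle", {
  p <- toy_protocol()
  set.seed(42)
  for (k in 1:3) {
    for (i in 1:60) {
      tr <- 1 + rnorm(50, 0, 0.02) +
        0.04 * (runif(50) < 0.15)          # spiky noise, borderline runs
      norm <- normalize_traces(tr * 700, p)
      got <- detect_responses(rbind(norm), NULL, p, min_run_frames = k)
      want <- oracle_detect(as.vector(norm), p, min_run = k)
      expect_identical(got$responded, want$responded)
      expect_identical(got$first_crossing_frame, want$first_frame)
    }
  }
})

test_that("repeatability responders are a subset of single-application
           responders and shrink with threshold", {
  p <- compact_protocol()
  cfg <- synth_config(seed = 31, field_area = c(120, 120),
                      class_fractions = c(A_only = 0.1, B_only = 0,
                                          both = 0),
                      respond_prob = 0.6, amp_range = c(4.5, 6))
  ds <- generate_trace_dataset(generate_knob_field(cfg), p, cfg)
  norm <- normalize_traces(ds$traces, p)
  calls <- detect_responses(norm, NULL, p)
  resp <- call_responders(calls, p)
  repeaters <- resp$knob_id[resp$stimulus == "A" & resp$responder]
  singles <- unique(calls$knob_id[calls$stimulus == "A" & calls$responded])
  expect_true(all(repeaters %in% singles))
  expect_lt(length(repeaters), length(singles))
  # raising the threshold multiplier never adds responders
  calls3 <- detect_responses(norm, NULL, p, threshold_mult = 3)
  resp3 <- call_responders(calls3, p)
  expect_lte(sum(resp3$responder), sum(resp$responder))
  expect_true(all(resp3$knob_id[resp3$responder] %in%
                    resp$knob_id[resp$responder]))
})

test_that("the responder call requires every application", {
  p <- default_protocol()
  expect_true(call_responder(c(TRUE, TRUE), p))
  expect_false(call_responder(c(TRUE, FALSE), p))
  expect_false(call_responder(c(TRUE, TRUE, FALSE), p))
  expect_error(call_responder(TRUE, p), "applications")
})
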
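# Independent brute-force oracles. These deliberately share no code with the
# package: explicit per-frame loops and rle-based run finding, so agreement
# with the vectorized implementation is a real check of the rule's semantics.

# compact two-stimulus protocol for large simulations: short inter-stimulus
# gaps (flagged by the protocol, harmless for null traces), full-length
# baseline and latency windows
compact_protocol <- function(n_applications = 2L) {
  onsets <- 55L + 45L * (seq_len(2L * n_applications) - 1L)
  stim_protocol(data.frame(stimulus = rep(c("A", "B"), n_applications),
                           onset_frame = onsets),
                min_isi_s = 0)
}

# exhaustive check of the response rule on one normalized trace
oracle_detect <- function(norm, protocol, threshold_mult = 2,
                          min_run = 3L) {
  fi <- protocol$frame_interval_s
  bw <- protocol$baseline_frames
  base <- norm[(bw[1] + 1):bw[2]]
  thr <- mean(base) + threshold_mult * sd(base)
  lat_frames <- floor(protocol$latency_window_s / fi)
  apps <- protocol$applications
  out <- data.frame(stimulus = apps$stimulus,
                    application_index = apps$application_index,
                    responded = FALSE, first_frame = NA_integer_)
  for (a in seq_len(nrow(apps))) {
    onset <- apps$onset_frame[a]
    run <- 0L
    for (f in onset:(onset + lat_frames)) {      # 0-based frames
      run <- if (norm[f + 1] > thr) run + 1L else 0L
      if (run == min_run) {
        out$responded[a] <- TRUE
        out$first_frame[a] <- f - min_run + 1L
        break
      }
    }
  }
  out
}

# direct Monte-Carlo of the null: iid Gaussian noise traces around F0 = 1,
# normalized and run through the rule via rle(); returns per-replicate
# responder flags (all applications of stimulus "A") and single-application
# flags (first application of "A")
oracle_null_mc <- function(n_rep, protocol, noise_sd = 0.02,
                           threshold_mult = 2, min_run = 3L, seed = 1) {
  set.seed(seed)
  fi <- protocol$frame_interval_s
  bw <- protocol$baseline_frames
  lat_frames <- floor(protocol$latency_window_s / fi)
  apps <- protocol$applications[protocol$applications$stimulus == "A", ]
  responder <- single <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    raw <- 1 + rnorm(protocol$n_frames, 0, noise_sd)
    norm <- raw / mean(raw[(bw[1] + 1):bw[2]])
    base <- norm[(bw[1] + 1):bw[2]]
    thr <- mean(base) + threshold_mult * sd(base)
    hit <- logical(nrow(apps))
    for (a in seq_len(nrow(apps))) {
      w <- norm[(apps$onset_frame[a] + 1):(apps$onset_frame[a] + 1 + lat_frames)]
      rl <- rle(w > thr)
      hit[a] <- any(rl$values & rl$lengths >= min_run)
    }
    responder[r] <- all(hit)
    single[r] <- hit[1]
  }
  list(responder_rate = mean(responder), single_rate = mean(single),
       n = n_rep)
}
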
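#' Configuration for the synthetic recording generator
#'
#' Bundles every tunable of the synthetic en face imaging generator with the
#' study-scale defaults: knob fields at 8.32 knobs/100 um^2, responder class
#' fractions of 1.6% (both stimuli), 0.5% (A only) and 0.1% (B only) of all
#' knobs, Gaussian baseline noise of 2% of F0, and double-exponential
#' Ca2+ transients (rise tau 3 s, decay tau 15 s) whose peaks are drawn in
#' multiples of the noise SD.
#'
#' @param seed integer seed; every generator draw flows from it.
#' @param field_area `c(width_um, height_um)` of the recorded field.
#' @param knob_density knobs per 100 um^2.
#' @param class_fractions named fractions of all knobs for `A_only`,
#'   `B_only` and `both` responder classes (non-negative, summing to <= 1).
#' @param noise_sd per-frame Gaussian noise SD as a fraction of F0.
#' @param bleach_slope linear bleaching, fraction of F0 per frame (default 0).
#' @param amp_range transient peak amplitude range in multiples of
#'   `noise_sd`; the minimum must exceed 2 or planted responders would be
#'   sub-threshold by construction.
#' @param rise_tau_s,decay_tau_s transient kinetics in seconds.
#' @param latency_range_s response onset latency after application onset.
#' @param respond_prob probability that a planted responder fires on any
#'   given application of its stimulus (1 = always, so the repeatability
#'   criterion is satisfied by construction).
#' @param f0_range range of true resting fluorescence (arbitrary units).
#' @param amp_ref_sd reference SD (fraction of F0) in which `amp_range` is
#'   expressed; defaults to `noise_sd`. Set explicitly for noiseless
#'   traces, where amplitudes would otherwise degenerate to zero.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         field_area = c(160, 160),
                         knob_density = 8.32,
                         class_fractions = c(A_only = 0.005, B_only = 0.001,
                                             both = 0.016),
                         noise_sd = 0.02,
                         bleach_slope = 0,
                         amp_range = c(5, 8),
                         rise_tau_s = 3,
                         decay_tau_s = 15,
                         latency_range_s = c(1.5, 6),
                         respond_prob = 1,
                         f0_range = c(500, 1500),
                         amp_ref_sd = NULL) {
  fr <- class_fractions[c("A_only", "B_only", "both")]
  if (any(is.na(fr))) stop("class_fractions needs names A_only, B_only, both")
  if (any(fr < 0) || sum(fr) > 1) stop("fractions must be >= 0 and sum <= 1")
  if (knob_density < 0) stop("knob_density must be non-negative")
  if (length(field_area) != 2) stop("field_area must be (width, height)")
  if (min(amp_range) <= 2)
    stop("amp_range minimum must exceed 2 noise SDs (threshold multiple)")
  if (respond_prob <= 0 || respond_prob > 1)
    stop("respond_prob must be in (0, 1]")
  if (noise_sd < 0 || bleach_slope < 0) stop("negative noise or bleach")
  if (is.null(amp_ref_sd)) amp_ref_sd <- noise_sd
  if (amp_ref_sd <= 0)
    stop("amp_ref_sd must be positive (set it explicitly when noise_sd = 0)")
  structure(list(seed = as.integer(seed), field_area = field_area,
                 knob_density = knob_density, class_fractions = fr,
                 noise_sd = noise_sd, bleach_slope = bleach_slope,
                 amp_range = amp_range, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, latency_range_s = latency_range_s,
                 respond_prob = respond_prob, f0_range = f0_range,
                 amp_ref_sd = amp_ref_sd),
            class = "synth_config")
}

#' Generate a field of knob positions
#'
#' Knobs are placed on a jittered hexagonal lattice whose spacing gives the
#' requested density; jitter is bounded so that no two knobs come closer
#' than 2 um (physical non-overlap of dendritic knobs). Expected count is
#' `density * area / 100`.
#'
#' @param config a [synth_config()].
#' @return data.frame `knob_id`, `x_um`, `y_um` with attribute `area_um2`.
#' @export
generate_knob_field <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  w <- config$field_area[1]; h <- config$field_area[2]
  if (w <= 0 || h <= 0) stop("field_area must be positive")
  d <- config$knob_density / 100            # knobs per um^2
  if (d == 0)
    return(structure(data.frame(knob_id = character(), x_um = numeric(),
                                y_um = numeric()),
                     area_um2 = w * h, field_dims_um = c(w, h)))
  set.seed(config$seed)
  a <- sqrt(2 / (sqrt(3) * d))              # lattice constant
  dy <- a * sqrt(3) / 2
  ys <- seq(dy / 2, h, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    xs <- seq(a / 2 + (i %% 2) * a / 2, w, by = a)
    cbind(xs, rep(ys[i], length(xs)))
  }))
  r <- if (a > 2) 0.4 * (a - 2) else 0      # keeps pairwise spacing >= 2 um
  n <- nrow(pts)
  rad <- r * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  x <- pts[, 1] + rad * cos(th); y <- pts[, 2] + rad * sin(th)
  keep <- x >= 0 & x < w & y >= 0 & y < h
  structure(data.frame(knob_id = sprintf("k%05d", seq_len(sum(keep))),
                       x_um = x[keep], y_um = y[keep]),
            area_um2 = w * h, field_dims_um = c(w, h))
}

transient_kernel <- function(t, rise, decay) {
  g <- (1 - exp(-t / rise)) * exp(-t / decay)
  tpk <- rise * log(1 + decay / rise)
  g / ((1 - exp(-tpk / rise)) * exp(-tpk / decay))
}

#' Generate raw fluorescence traces with planted responder classes
#'
#' Each knob receives a raw trace `F0_true * (1 - bleach_slope * frame) +
#' noise`, with iid Gaussian noise of SD `noise_sd * F0_true` per frame.
#' Responder classes (`A_only`, `B_only`, `both`, else `none`) are drawn
#' multinomially from `class_fractions`; on each application of a stimulus
#' in its class a responder fires with probability `respond_prob`, adding a
#' peak-normalized double-exponential transient whose peak (in multiples of
#' the noise SD) is drawn uniformly from `amp_range`, starting at onset plus
#' a uniform latency from `latency_range_s`.
#'
#' The generator is linear in `F0_true`: scaling `f0_range` scales raw
#' traces exactly and leaves normalized traces unchanged (same seed).
#'
#' @param field knob field from [generate_knob_field()].
#' @param protocol a [stim_protocol()] with two stimuli; the first label in
#'   `protocol$applications` order is class "A", the second "B".
#' @param config a [synth_config()].
#' @return list of class `trace_dataset`: `traces` (knobs x frames raw
#'   matrix), `knobs` (the field), `protocol`, and `truth` (list with
#'   `classes` data.frame `knob_id`, `class` and `events` data.frame of
#'   per-application fire events).
#' @export
generate_trace_dataset <- function(field, protocol, config) {
  stopifnot(inherits(config, "synth_config"),
            inherits(protocol, "stim_protocol"))
  stims <- unique(protocol$applications$stimulus)
  if (length(stims) != 2)
    stop("trace generator expects a two-stimulus protocol")
  n <- nrow(field); Tn <- protocol$n_frames; fi <- protocol$frame_interval_s
  set.seed(config$seed + 1L)
  cls <- if (n) sample(c("none", "A_only", "B_only", "both"), n, replace = TRUE,
                       prob = c(1 - sum(config$class_fractions),
                                config$class_fractions[c("A_only", "B_only",
                                                         "both")]))
         else character()
  f0 <- stats::runif(n, config$f0_range[1], config$f0_range[2])
  z <- matrix(stats::rnorm(n * Tn), n, Tn)
  tr <- z * (config$noise_sd * f0) + f0
  if (config$bleach_slope != 0)
    tr <- tr - f0 %o% (config$bleach_slope * (seq_len(Tn) - 1))
  # planted transients
  apps <- protocol$applications
  responds_to <- function(class, stim)
    (class == "both") | (class == "A_only" & stim == stims[1]) |
    (class == "B_only" & stim == stims[2])
  ev <- list()
  for (a in seq_len(nrow(apps))) {
    idx <- which(responds_to(cls, apps$stimulus[a]))
    if (!length(idx)) next
    fire <- stats::runif(length(idx)) <= config$respond_prob
    amp <- stats::runif(length(idx), config$amp_range[1], config$amp_range[2])
    lat <- stats::runif(length(idx), config$latency_range_s[1],
                        config$latency_range_s[2])
    ev[[a]] <- data.frame(knob_id = field$knob_id[idx],
                          stimulus = apps$stimulus[a],
                          application_index = apps$application_index[a],
                          fired = fire, amp_sd = amp, latency_s = lat)
    t0 <- apps$onset_frame[a] * fi + lat
    for (j in which(fire)) {
      k <- idx[j]
      frames <- which((seq_len(Tn) - 1) * fi >= t0[j])
      if (!length(frames)) next
      tt <- (frames - 1) * fi - t0[j]
      tr[k, frames] <- tr[k, frames] +
        f0[k] * config$amp_ref_sd * amp[j] *
        transient_kernel(tt, config$rise_tau_s, config$decay_tau_s)
    }
  }
  rownames(tr) <- field$knob_id
  truth <- list(classes = data.frame(knob_id = field$knob_id, class = cls),
                events = if (length(ev)) do.call(rbind, ev) else
                  data.frame(knob_id = character(), stimulus = character(),
                             application_index = integer(), fired = logical(),
                             amp_sd = numeric(), latency_s = numeric()))
  structure(list(traces = tr, knobs = field, protocol = protocol,
                 truth = truth, stimuli = stims),
            class = "trace_dataset")
}

#' Render a knob field as a synthetic image stack
#'
#' Each knob is drawn as an isotropic Gaussian spot (`sigma = psf_sigma_um`)
#' whose peak intensity at each frame equals the knob's trace value, on a
#' constant background. Integrated spot intensity is proportional to the
#' trace value.
#'
#' @param field knob field from [generate_knob_field()].
#' @param traces raw trace matrix aligned with `field` rows (or `NULL` for a
#'   single all-ones frame).
#' @param psf_sigma_um spot SD in um.
#' @param pixel_um pixel size in um.
#' @param frames frame indices (1-based columns of `traces`) to render.
#' @param background constant background level.
#' @return numeric array `[y, x, frame]` with attribute `pixel_um`.
#' @export
render_stack <- function(field, traces = NULL, psf_sigma_um = 0.6,
                         pixel_um = 0.25, frames = NULL,
                         background = 0) {
  if (pixel_um <= 0) stop("pixel_um must be positive")
  dims <- attr(field, "field_dims_um")
  if (is.null(dims)) dims <- c(max(field$x_um, 1) + 3 * psf_sigma_um,
                               max(field$y_um, 1) + 3 * psf_sigma_um)
  nx <- as.integer(ceiling(dims[1] / pixel_um))
  ny <- as.integer(ceiling(dims[2] / pixel_um))
  if (is.null(traces)) traces <- matrix(1, nrow(field), 1)
  if (is.null(frames)) frames <- seq_len(ncol(traces))
  out <- array(background, dim = c(ny, nx, length(frames)))
  if (nrow(field)) {
    sig <- psf_sigma_um / pixel_um
    half <- ceiling(4 * sig)
    px <- field$x_um / pixel_um + 0.5; py <- field$y_um / pixel_um + 0.5
    for (f in seq_along(frames)) {
      img <- out[, , f]
      for (k in seq_len(nrow(field))) {
        cx <- px[k]; cy <- py[k]
        xs <- max(1, floor(cx - half)):min(nx, ceiling(cx + half))
        ys <- max(1, floor(cy - half)):min(ny, ceiling(cy + half))
        g <- exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sig^2))
        img[ys, xs] <- img[ys, xs] + traces[k, frames[f]] * g
      }
      out[, , f] <- img
    }
  }
  structure(out, pixel_um = pixel_um)
}

#' Generate a cohort of investigation-bout sessions
#'
#' Per mouse and stimulus side, bout counts are Poisson(`bout_rate`) and
#' bout durations Gamma(shape 2) with mean `bout_mean_s`; durations on side
#' A are scaled by `2^planted_mu`, so the expected investigation-time ratio
#' A/B is `2^planted_mu`. Bouts are laid out non-overlapping within the
#' session. Defaults are calibrated to the study scale: a 10-min session,
#' ~30 s of baseline investigation per side, and per-animal preference-score
#' SD near 0.9.
#'
#' @param n_mice number of subjects.
#' @param planted_mu true log2 investigation-time ratio (A over B).
#' @param bout_rate expected bouts per side per session.
#' @param bout_mean_s mean bout duration (side B) in seconds.
#' @param session_length_s session length (default 600 s).
#' @param seed integer seed.
#' @return data.frame of bouts: `subject_id`, `label` ("A"/"B"), `start_s`,
#'   `stop_s`, with attribute `session_length_s`.
#' @export
generate_behavior_cohort <- function(n_mice, planted_mu = 0.81,
                                     bout_rate = 10, bout_mean_s = 3,
                                     session_length_s = 600, seed = 1L) {
  if (n_mice < 1) stop("n_mice must be >= 1")
  set.seed(seed)
  shape <- 2
  res <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    nA <- stats::rpois(1, bout_rate); nB <- stats::rpois(1, bout_rate)
    dA <- stats::rgamma(nA, shape, scale = bout_mean_s / shape) * 2^planted_mu
    dB <- stats::rgamma(nB, shape, scale = bout_mean_s / shape)
    dur <- c(dA, dB); lab <- c(rep("A", nA), rep("B", nB))
    ord <- sample(seq_along(dur)); dur <- dur[ord]; lab <- lab[ord]
    tot <- sum(dur)
    if (tot >= session_length_s)
      stop("bout durations exceed the session; lower bout_rate or bout_mean_s")
    gaps <- stats::rexp(length(dur) + 1)
    gaps <- gaps / sum(gaps) * (session_length_s - tot)
    starts <- cumsum(gaps)[seq_along(dur)] +
      c(0, cumsum(dur))[seq_along(dur)]
    res[[i]] <- data.frame(subject_id = sprintf("m%02d", i), label = lab,
                           start_s = starts, stop_s = starts + dur)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "session_length_s") <- session_length_s
  out
}

#' Generate region count tables for activity mapping
#'
#' Per region, total (DAPI) counts are Poisson(`dapi_rate * area`) and
#' positive counts Binomial(total, `p_positive`); emulates pS6/c-Fos
#' quantification input.
#'
#' @param n_regions number of regions (sections) to generate.
#' @param area_um2 region area in um^2 (recycled).
#' @param dapi_rate total-cell density per um^2.
#' @param p_positive per-cell probability of being positive.
#' @param subject_id subject label stamped on every region.
#' @param seed integer seed.
#' @return data.frame `subject_id`, `region_label`, `area_um2`,
#'   `dapi_count`, `positive_count`.
#' @export
generate_count_regions <- function(n_regions, area_um2 = 20000,
                                   dapi_rate = 0.05, p_positive = 0.0219,
                                   subject_id = "s1", seed = 1L) {
  if (p_positive < 0 || p_positive > 1) stop("p_positive must be in [0, 1]")
  set.seed(seed)
  area <- rep_len(area_um2, n_regions)
  dapi <- stats::rpois(n_regions, dapi_rate * area)
  pos <- stats::rbinom(n_regions, dapi, p_positive)
  data.frame(subject_id = subject_id,
             region_label = sprintf("r%02d", seq_len(n_regions)),
             area_um2 = area, dapi_count = dapi, positive_count = pos)
}
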
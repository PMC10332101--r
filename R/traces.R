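#' Normalize knob fluorescence traces to baseline (F/F0)
#'
#' Each knob's raw trace is divided by its F0, the mean raw fluorescence
#' over the protocol's baseline window (by default the first 50 frames).
#' Normalization is scale invariant: `c * F` normalizes identically for any
#' `c > 0`.
#'
#' @param traces numeric matrix, knobs in rows, frames in columns (row names
#'   are knob ids), or a numeric vector for a single knob.
#' @param protocol a [stim_protocol()].
#' @return A matrix (or vector) of F/F0 ratios with an attribute `F0` holding
#'   the per-knob baseline fluorescence.
#' @export
normalize_traces <- function(traces, protocol) {
  vec <- is.null(dim(traces))
  m <- if (vec) matrix(traces, nrow = 1) else as.matrix(traces)
  if (!is.null(rownames(traces)) && !vec) rownames(m) <- rownames(traces)
  bw <- protocol$baseline_frames
  if (ncol(m) < bw[2])
    stop("trace length ", ncol(m), " does not cover the baseline window")
  if (any(!is.finite(m)))
    stop("non-finite fluorescence values in trace(s): ",
         paste(utils::head(which(rowSums(!is.finite(m)) > 0), 5), collapse = ", "))
  f0 <- rowMeans(m[, (bw[1] + 1L):bw[2], drop = FALSE])
  bad <- !is.finite(f0) | f0 <= 0
  if (any(bad))
    stop("non-positive F0 for knob(s): ",
         paste(utils::head(rownames(m)[bad] %||% which(bad), 5), collapse = ", "))
  out <- m / f0
  if (vec) { out <- drop(out); attr(out, "F0") <- unname(f0) }
  else attr(out, "F0") <- f0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline mean and noise SD of normalized traces
#'
#' The response threshold is anchored on the baseline fluorescence noise:
#' per knob, the mean and sample standard deviation (denominator n - 1) of
#' the normalized trace over the baseline window.
#'
#' @inheritParams normalize_traces
#' @param norm normalized trace matrix (or vector) from [normalize_traces()].
#' @return data.frame with columns `mean_b`, `sd_b`, one row per knob.
#' @export
baseline_stats <- function(norm, protocol) {
  m <- if (is.null(dim(norm))) matrix(norm, nrow = 1) else as.matrix(norm)
  bw <- protocol$baseline_frames
  n <- bw[2] - bw[1]
  if (n < 2) stop("baseline window must contain at least 2 frames")
  b <- m[, (bw[1] + 1L):bw[2], drop = FALSE]
  mu <- rowMeans(b)
  sdv <- sqrt(pmax(rowSums((b - mu)^2), 0) / (n - 1))
  data.frame(mean_b = mu, sd_b = sdv, row.names = rownames(m))
}

# first column index, per row, of a run of >= k consecutive TRUEs; NA if none
first_run_start <- function(A, k) {
  n <- nrow(A); m <- ncol(A)
  if (m < k) return(rep(NA_integer_, n))
  S <- A[, 1:(m - k + 1L), drop = FALSE]
  if (k > 1) for (j in 2:k) S <- S & A[, j:(m - k + j), drop = FALSE]
  has <- rowSums(S) > 0
  idx <- max.col(S * 1L, ties.method = "first")
  ifelse(has, idx, NA_integer_)
}

row_max <- function(A) {
  out <- A[, 1]
  if (ncol(A) > 1) for (j in 2:ncol(A)) out <- pmax(out, A[, j])
  out
}

#' Call per-application responses against the baseline-noise threshold
#'
#' A response to one stimulus application is a stimulus-dependent deviation
#' of the normalized trace that (i) exceeds `mean_b + threshold_mult * sd_b`
#' and (ii) begins within `latency_window_s` of application onset. To
#' distinguish a calcium transient (supra-threshold for many consecutive
#' frames at these kinetics) from single-frame baseline noise excursions,
#' the crossing must be sustained for `min_run_frames` consecutive frames;
#' `min_run_frames = 1` gives the literal first-crossing rule. Latency is
#' the time from onset to the first frame of the first qualifying run; peak
#' amplitude is the maximum of the normalized trace over the latency window.
#' Each application is searched independently.
#'
#' @param norm normalized trace matrix (knobs x frames) or vector.
#' @param bstats baseline statistics from [baseline_stats()] (recomputed if
#'   `NULL`).
#' @param protocol a [stim_protocol()].
#' @param threshold_mult multiple of the baseline noise SD defining the
#'   threshold (default 2).
#' @param min_run_frames consecutive supra-threshold frames required
#'   (default 3, i.e. 4.5 s at 1.5-s frames).
#' @param threshold_floor absolute lower bound on the threshold offset
#'   above `mean_b` (default 1e-6 normalized units), so a numerically
#'   zero-noise baseline does not make every infinitesimal excursion a
#'   response.
#' @return data.frame of response calls: `knob_id`, `stimulus`,
#'   `application_index`, `responded`, `first_crossing_frame` (0-based, NA
#'   when no response), `latency_s`, `peak_amplitude`.
#' @export
detect_responses <- function(norm, bstats = NULL, protocol,
                             threshold_mult = 2, min_run_frames = 3L,
                             threshold_floor = 1e-6) {
  m <- if (is.null(dim(norm))) matrix(norm, nrow = 1) else as.matrix(norm)
  if (is.null(bstats)) bstats <- baseline_stats(m, protocol)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  fi <- protocol$frame_interval_s
  lat_frames <- floor(protocol$latency_window_s / fi)
  thr <- bstats$mean_b + pmax(threshold_mult * bstats$sd_b, threshold_floor)
  apps <- protocol$applications
  out <- vector("list", nrow(apps))
  for (a in seq_len(nrow(apps))) {
    onset <- apps$onset_frame[a]
    last <- onset + lat_frames
    if (last + 1L > ncol(m))
      stop("application at frame ", onset, " plus latency window exceeds the ",
           ncol(m), "-frame trace")
    w <- m[, (onset + 1L):(last + 1L), drop = FALSE]   # 0-based -> R columns
    above <- w > thr
    start <- first_run_start(above, as.integer(min_run_frames))
    responded <- !is.na(start)
    first_frame <- ifelse(responded, onset + start - 1L, NA_integer_)
    out[[a]] <- data.frame(
      knob_id = ids,
      stimulus = apps$stimulus[a],
      application_index = apps$application_index[a],
      responded = responded,
      first_crossing_frame = first_frame,
      latency_s = (first_frame - onset) * fi,
      peak_amplitude = row_max(w),
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' @rdname detect_responses
#' @param application row index into `protocol$applications` selecting a
#'   single application.
#' @export
detect_response <- function(norm, bstats = NULL, application, protocol,
                            threshold_mult = 2, min_run_frames = 3L) {
  calls <- detect_responses(norm, bstats, protocol, threshold_mult,
                            min_run_frames)
  apps <- protocol$applications
  calls[calls$stimulus == apps$stimulus[application] &
          calls$application_index == apps$application_index[application], ,
        drop = FALSE]
}

#' Repeatability criterion: responder calls per knob and stimulus
#'
#' A knob is a responder to a stimulus only if it responded during *every*
#' application of that stimulus (the generalization of "both applications"
#' to protocols with more than two).
#'
#' @param calls response-call table from [detect_responses()].
#' @param protocol a [stim_protocol()].
#' @return data.frame `knob_id`, `stimulus`, `n_applications`, `n_responded`,
#'   `responder` (logical).
#' @export
call_responders <- function(calls, protocol) {
  need <- protocol$min_applications
  key <- paste(calls$knob_id, calls$stimulus, sep = "\r")
  n_resp <- rowsum(as.integer(calls$responded), key)
  n_app <- rowsum(rep(1L, nrow(calls)), key)
  km <- do.call(rbind, strsplit(rownames(n_resp), "\r", fixed = TRUE))
  n_app <- drop(n_app); n_resp <- drop(n_resp)
  if (any(n_app < need))
    stop("fewer than ", need, " applications recorded for some knob/stimulus")
  data.frame(knob_id = km[, 1], stimulus = km[, 2],
             n_applications = n_app, n_responded = n_resp,
             responder = n_resp == n_app, row.names = NULL)
}

#' @rdname call_responders
#' @param responded logical vector of per-application outcomes for one knob
#'   and stimulus.
#' @export
call_responder <- function(responded, protocol) {
  if (length(responded) < protocol$min_applications)
    stop("fewer than ", protocol$min_applications, " applications supplied")
  all(responded)
}
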
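#' Stimulus protocol for time-lapse knob imaging
#'
#' Describes the temporal structure of a recording: frame interval, the
#' baseline window used for F0 normalization and noise estimation, and the
#' stimulus applications. All frame indices are 0-based (matching the frame
#' column of on-disk trace tables); times in seconds are `frame *
#' frame_interval_s`. Windows are half-open `[start, end)` in frames.
#'
#' @param applications data.frame with columns `stimulus` (character label),
#'   `onset_frame` (0-based frame of application onset) and optionally
#'   `duration_s` (defaults to 30 s).
#' @param frame_interval_s acquisition interval in seconds (default 1.5 s).
#' @param baseline_frames half-open frame range used for F0 and baseline
#'   noise, default `c(0, 50)` (the first 50 frames).
#' @param latency_window_s a response must begin within this many seconds of
#'   application onset (default 60 s).
#' @param min_applications minimum applications per stimulus for a responder
#'   call (default 2).
#' @param min_isi_s inter-onset interval below which a warning is emitted
#'   (default 240 s). Short intervals are permitted (synthetic stress tests
#'   use them) but flagged.
#' @param n_frames total frames of the recording; defaults to the smallest
#'   length covering all latency windows.
#'
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(applications,
                          frame_interval_s = 1.5,
                          baseline_frames = c(0L, 50L),
                          latency_window_s = 60,
                          min_applications = 2L,
                          min_isi_s = 240,
                          n_frames = NULL) {
  if (!is.data.frame(applications) ||
      !all(c("stimulus", "onset_frame") %in% names(applications)))
    stop("`applications` must be a data.frame with columns stimulus, onset_frame")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be positive")
  if (length(baseline_frames) != 2L || baseline_frames[2] <= baseline_frames[1])
    stop("`baseline_frames` must be an increasing pair [start, end)")
  apps <- applications
  if (is.null(apps$duration_s)) apps$duration_s <- 30
  apps <- apps[order(apps$onset_frame), , drop = FALSE]
  rownames(apps) <- NULL
  if (any(apps$onset_frame < baseline_frames[2]))
    stop("baseline window must precede the first application onset")
  tab <- table(apps$stimulus)
  if (any(tab < min_applications))
    stop("every stimulus needs >= ", min_applications, " applications; short: ",
         paste(names(tab)[tab < min_applications], collapse = ", "))
  # application index within each stimulus, in onset order
  apps$application_index <- stats::ave(seq_len(nrow(apps)), apps$stimulus,
                                       FUN = seq_along)
  isi <- diff(apps$onset_frame) * frame_interval_s
  if (length(isi) && any(isi < min_isi_s))
    warning("inter-onset interval below ", min_isi_s,
            " s for some applications (", paste(round(isi[isi < min_isi_s]),
            collapse = ", "), " s)")
  lat_frames <- floor(latency_window_s / frame_interval_s)
  need <- max(apps$onset_frame + lat_frames) + 1L
  if (is.null(n_frames)) n_frames <- need
  if (n_frames < need)
    stop("`n_frames` (", n_frames, ") does not cover the last latency window (",
         need, " frames needed)")
  structure(list(frame_interval_s = frame_interval_s,
                 baseline_frames = as.integer(baseline_frames),
                 applications = apps,
                 latency_window_s = latency_window_s,
                 min_applications = as.integer(min_applications),
                 min_isi_s = min_isi_s,
                 n_frames = as.integer(n_frames)),
            class = "stim_protocol")
}

#' Default two-stimulus protocol
#'
#' Two stimuli (`A`, `B`), two 30-s applications each, alternating with
#' 4-min inter-onset intervals, 1.5-s frames, 50 baseline frames: the
#' recording structure that the response criteria assume.
#'
#' @param stimuli character vector of two stimulus labels.
#' @param n_applications applications per stimulus (default 2).
#' @param isi_s inter-onset interval in seconds (default 240).
#' @return A `stim_protocol`.
#' @export
default_protocol <- function(stimuli = c("A", "B"), n_applications = 2L,
                             isi_s = 240) {
  fi <- 1.5
  n_apps <- n_applications * length(stimuli)
  onsets <- 60L + round(isi_s / fi) * (seq_len(n_apps) - 1L)
  apps <- data.frame(stimulus = rep(stimuli, n_applications),
                     onset_frame = as.integer(onsets))
  stim_protocol(apps, frame_interval_s = fi, min_isi_s = min(isi_s, 240))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Stimulus protocol:", x$n_frames, "frames @", x$frame_interval_s, "s\n")
  cat("  baseline frames [", x$baseline_frames[1], ",", x$baseline_frames[2],
      "), latency window", x$latency_window_s, "s\n")
  cat("  applications:\n")
  print(x$applications, ...)
  invisible(x)
}

#' Read / write a protocol as YAML
#'
#' @param protocol a `stim_protocol`.
#' @param path file path.
#' @return `read_protocol` returns a `stim_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  x <- unclass(protocol)
  x$applications <- as.list(x$applications[c("stimulus", "onset_frame",
                                             "duration_s")])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  stim_protocol(as.data.frame(x$applications, stringsAsFactors = FALSE),
                frame_interval_s = x$frame_interval_s,
                baseline_frames = unlist(x$baseline_frames),
                latency_window_s = x$latency_window_s,
                min_applications = x$min_applications,
                min_isi_s = x$min_isi_s,
                n_frames = x$n_frames)
}
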
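#' Total investigation time per stimulus side
#'
#' Sums bout durations per stimulus label for one session. Bouts of the
#' same subject must not overlap (a mouse investigates one source at a
#' time).
#'
#' @param session data.frame of bouts: `label`, `start_s`, `stop_s`
#'   (one subject).
#' @param labels the two stimulus labels (default `c("A", "B")`).
#' @return named numeric `c(IT_A, IT_B)` in seconds (names follow
#'   `labels`).
#' @export
investigation_times <- function(session, labels = c("A", "B")) {
  if (nrow(session)) {
    if (any(session$stop_s <= session$start_s))
      stop("bout stop must exceed start")
    o <- order(session$start_s)
    s <- session[o, ]
    if (any(s$start_s[-1] < s$stop_s[-nrow(s)]))
      stop("overlapping bouts in session",
           if (!is.null(session$subject_id)) paste0(" for subject ",
                                                    session$subject_id[1]))
  }
  vapply(labels, function(l)
    sum(session$stop_s[session$label == l] -
          session$start_s[session$label == l]), 0)
}

#' Preference score: log2 investigation-time ratio
#'
#' `log2(IT_A / IT_B)`. Positive scores mean preference for side A,
#' negative for side B; the score is antisymmetric under swapping sides.
#' Zero investigation times are an error under the default `"strict"`
#' policy; the `"epsilon"` policy adds `epsilon` seconds to both times and
#' flags the value.
#'
#' @param it_a,it_b investigation times in seconds.
#' @param zero_policy `"strict"` or `"epsilon"`.
#' @param epsilon seconds added to both times under the epsilon policy.
#' @return numeric score, with attribute `epsilon_applied` when smoothing
#'   was used.
#' @export
preference_score <- function(it_a, it_b, zero_policy = c("strict", "epsilon"),
                             epsilon = 0.5) {
  zero_policy <- match.arg(zero_policy)
  if (it_a < 0 || it_b < 0) stop("investigation times must be non-negative")
  if (it_a == 0 || it_b == 0) {
    if (zero_policy == "strict")
      stop("zero investigation time; use zero_policy = \"epsilon\" to smooth")
    return(structure(log2((it_a + epsilon) / (it_b + epsilon)),
                     epsilon_applied = TRUE))
  }
  log2(it_a / it_b)
}

#' Per-subject preference scores for a cohort of sessions
#'
#' @param bouts bout table with `subject_id`, `label`, `start_s`, `stop_s`.
#' @param labels the two stimulus labels, A first.
#' @inheritParams preference_score
#' @return data.frame `subject_id`, `it_a`, `it_b`, `score`.
#' @export
score_sessions <- function(bouts, labels = c("A", "B"),
                           zero_policy = c("strict", "epsilon"),
                           epsilon = 0.5) {
  zero_policy <- match.arg(zero_policy)
  subj <- unique(bouts$subject_id)
  res <- lapply(subj, function(s) {
    it <- investigation_times(bouts[bouts$subject_id == s, ], labels)
    data.frame(subject_id = s, it_a = it[[1]], it_b = it[[2]],
               score = as.numeric(preference_score(it[[1]], it[[2]],
                                                   zero_policy, epsilon)))
  })
  do.call(rbind, res)
}

#' Group preference: mean, SEM and one-sample test against zero
#'
#' The group statistic is the mean of per-animal scores (not the score of
#' the group-mean times), with a two-sided one-sample t-test against 0.
#'
#' @param scores numeric vector of per-subject preference scores.
#' @return list of class `group_preference`: `mean`, `sem`, `n`, `test`
#'   (a [one_sample_vs_zero()] result).
#' @export
group_preference <- function(scores) {
  if (length(scores) < 2) stop("need at least two subjects")
  structure(list(mean = mean(scores),
                 sem = stats::sd(scores) / sqrt(length(scores)),
                 n = length(scores),
                 test = one_sample_vs_zero(scores)),
            class = "group_preference")
}

#' @export
print.group_preference <- function(x, ...) {
  cat(sprintf("Preference score: %.3f +/- %.3f (n = %d), %s p = %.4g\n",
              x$mean, x$sem, x$n, x$test$test_name, x$test$p_value))
  invisible(x)
}

#' Convert point start/stop event rows to bouts
#'
#' Many ethogram scorers export one row per event; rows alternate
#' START/STOP per subject and label. Pairs them into bouts.
#'
#' @param events data.frame `subject_id`, `label`, `event` ("START" or
#'   "STOP"), `time_s`.
#' @return bout table `subject_id`, `label`, `start_s`, `stop_s`.
#' @export
bouts_from_events <- function(events) {
  res <- list()
  for (key in unique(paste(events$subject_id, events$label))) {
    e <- events[paste(events$subject_id, events$label) == key, ]
    e <- e[order(e$time_s), ]
    if (nrow(e) %% 2 || !all(e$event == rep(c("START", "STOP"),
                                            nrow(e) / 2)))
      stop("unpaired START/STOP events for ", key)
    i <- seq(1, nrow(e), by = 2)
    res[[key]] <- data.frame(subject_id = e$subject_id[1],
                             label = e$label[1],
                             start_s = e$time_s[i], stop_s = e$time_s[i + 1])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$subject_id, out$start_s), ]
}
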
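#' Write and read long-format trace tables
#'
#' Trace tables are plain CSV with one row per knob and frame: `site_id`,
#' `knob_id`, `frame` (0-based), `fluorescence`. `read_trace_table`
#' rebuilds the knobs-by-frames matrix (rows ordered by first appearance,
#' columns by frame index).
#'
#' @param traces knobs-by-frames numeric matrix, row names = knob ids.
#' @param path CSV file path.
#' @param site_id site label stamped on every row.
#' @return `write_trace_table` returns `path` invisibly;
#'   `read_trace_table` returns a matrix with attribute `site_id`.
#' @export
write_trace_table <- function(traces, path, site_id = "site1") {
  ids <- rownames(traces) %||% as.character(seq_len(nrow(traces)))
  long <- data.frame(site_id = site_id,
                     knob_id = rep(ids, times = ncol(traces)),
                     frame = rep(0:(ncol(traces) - 1), each = nrow(traces)),
                     fluorescence = as.vector(traces))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "knob_id", "frame", "fluorescence")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("trace table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(long$knob_id)
  frames <- sort(unique(long$frame))
  m <- matrix(NA_real_, length(ids), length(frames),
              dimnames = list(ids, NULL))
  m[cbind(match(long$knob_id, ids), match(long$frame, frames))] <-
    long$fluorescence
  if (anyNA(m)) stop("trace table is ragged: missing knob/frame combinations")
  structure(m, site_id = long$site_id[1])
}

#' Write / read a grayscale image stack as multi-page TIFF
#'
#' Frames are scaled jointly to [0, 1] by the stack maximum before writing
#' 16-bit pages (relative intensities, which is all downstream detection
#' uses, are preserved); reading returns the array on that [0, 1] scale.
#'
#' @param stack numeric array `[y, x, frame]` (a matrix is one frame).
#' @param path TIFF file path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns the array.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  mx <- max(stack)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Read an investigation-bout table
#'
#' CSV with columns `subject_id`, `label`, `start_s`, `stop_s`; or, with
#' `events = TRUE`, an event-row export (`subject_id`, `label`, `event`,
#' `time_s`) that is converted via [bouts_from_events()].
#'
#' @param path CSV path.
#' @param events whether the file holds point events rather than bouts.
#' @return bout data.frame.
#' @export
read_bouts <- function(path, events = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (events) c("subject_id", "label", "event", "time_s")
          else c("subject_id", "label", "start_s", "stop_s")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("bout table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (events) bouts_from_events(x) else x
}

#' Read a region count table
#'
#' CSV with columns `subject_id`, `region_label`, `area_um2`,
#' `positive_count` and optionally `dapi_count`.
#'
#' @param path CSV path.
#' @return data.frame of count regions.
#' @export
read_count_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region_label", "area_um2", "positive_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  x
}
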
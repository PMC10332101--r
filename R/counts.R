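#' Percent positive cells of DAPI-stained total
#'
#' Per region, `100 * positive / dapi`. With `per_subject = TRUE` the
#' region table is reduced to one value per subject, the unweighted mean of
#' that subject's regions (sections); an area-weighted mean weights each
#' region by `area_um2`.
#'
#' @param regions data.frame with `positive_count`, `dapi_count`, and for
#'   aggregation `subject_id` (plus `area_um2` when weighting).
#' @param per_subject aggregate regions to one value per subject.
#' @param weight `"none"` (unweighted, default) or `"area"`.
#' @return numeric percent per region, or data.frame `subject_id`,
#'   `percent_positive` when `per_subject = TRUE`.
#' @export
percent_positive <- function(regions, per_subject = FALSE,
                             weight = c("none", "area")) {
  weight <- match.arg(weight)
  if (is.null(regions$dapi_count) || any(is.na(regions$dapi_count)))
    stop("dapi_count is required for percent-positive quantification")
  if (any(regions$dapi_count <= 0)) stop("dapi_count must be positive")
  if (any(regions$positive_count > regions$dapi_count))
    stop("positive_count exceeds dapi_count")
  pct <- 100 * regions$positive_count / regions$dapi_count
  if (!per_subject) return(pct)
  w <- if (weight == "area") regions$area_um2 else rep(1, nrow(regions))
  agg <- rowsum(data.frame(wp = w * pct, w = w), regions$subject_id)
  data.frame(subject_id = rownames(agg),
             percent_positive = agg$wp / agg$w, row.names = NULL)
}

#' Positive-cell density per square micrometer
#'
#' @param regions data.frame with `positive_count` and `area_um2` (plus
#'   `subject_id` for aggregation).
#' @inheritParams percent_positive
#' @return cells per um^2, per region or per subject.
#' @export
density_per_area <- function(regions, per_subject = FALSE,
                             weight = c("none", "area")) {
  weight <- match.arg(weight)
  if (any(regions$area_um2 <= 0)) stop("region area must be positive")
  dens <- regions$positive_count / regions$area_um2
  if (!per_subject) return(dens)
  w <- if (weight == "area") regions$area_um2 else rep(1, nrow(regions))
  agg <- rowsum(data.frame(wd = w * dens, w = w), regions$subject_id)
  data.frame(subject_id = rownames(agg),
             density_per_um2 = agg$wd / agg$w, row.names = NULL)
}

#' Percent reduction of a test value relative to control
#'
#' `100 * (control - test) / control`, rounded half away from zero to
#' `digits` decimals (0 = whole percent, the headline convention).
#'
#' @param control_value,test_value group summary values (control > 0).
#' @param digits decimals of the reported percent.
#' @return percent reduction (negative = increase).
#' @export
percent_reduction <- function(control_value, test_value, digits = 0) {
  if (control_value <= 0) stop("control value must be positive")
  round_half_away(100 * (control_value - test_value) / control_value, digits)
}
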
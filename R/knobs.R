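#' Round half away from zero
#'
#' The rounding convention for headline shares, folds and densities (R's
#' `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  g <- outer(-half:half, -half:half, function(y, x) {
    r2 <- x^2 + y^2
    (r2 / sigma^2 - 2) * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)   # zero-DC band-pass
}

#' Detect knob-like spots in a still fluorescence image
#'
#' Multiscale Laplacian-of-Gaussian blob detection: the image is convolved
#' with scale-normalized LoG kernels at a few sigmas between `min_sigma_um`
#' and `max_sigma_um`, local maxima of the (sign-flipped, so bright blobs
#' are positive) response above `threshold_rel` times the global maximum
#' response are kept, and detections closer than 2 um to a stronger one are
#' suppressed. Deterministic for a fixed input.
#'
#' @param image 2-D numeric matrix (grayscale, rows = y).
#' @param min_sigma_um,max_sigma_um spot-scale search range in um.
#' @param threshold_rel detection threshold relative to the strongest blob
#'   response in the image.
#' @param pixel_um pixel size in um.
#' @param suppression_um minimum spacing between detections (default 2 um,
#'   the physical knob diameter floor).
#' @return data.frame `x_um`, `y_um`, `sigma_um`, `response`, strongest
#'   first; empty for a blank image.
#' @export
detect_knobs <- function(image, min_sigma_um = 0.4, max_sigma_um = 1.2,
                         threshold_rel = 0.1, pixel_um,
                         suppression_um = 2) {
  if (missing(pixel_um) || pixel_um <= 0) stop("pixel_um must be positive")
  img <- as.matrix(image)
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      sigma_um = numeric(), response = numeric())
  if (!length(img) || max(img) == min(img)) return(empty)
  sigmas <- exp(seq(log(min_sigma_um), log(max_sigma_um), length.out = 4)) /
    pixel_um
  resp <- lapply(sigmas, function(s)
    -s^2 * EBImage::filter2(img, log_kernel(s), boundary = "replicate"))
  gmax <- max(vapply(resp, max, 0))
  if (gmax <= 0) return(empty)
  thr <- threshold_rel * gmax
  cand <- list()
  for (i in seq_along(resp)) {
    r <- resp[[i]]
    nr <- nrow(r); nc <- ncol(r)
    core <- r[2:(nr - 1), 2:(nc - 1)]
    # >= so symmetric plateaus still yield maxima; duplicates on a plateau
    # are merged by the non-maximum suppression below
    ismax <- core >= thr &
      core >= r[1:(nr - 2), 2:(nc - 1)] & core >= r[3:nr, 2:(nc - 1)] &
      core >= r[2:(nr - 1), 1:(nc - 2)] & core >= r[2:(nr - 1), 3:nc] &
      core >= r[1:(nr - 2), 1:(nc - 2)] & core >= r[1:(nr - 2), 3:nc] &
      core >= r[3:nr, 1:(nc - 2)] & core >= r[3:nr, 3:nc]
    w <- which(ismax, arr.ind = TRUE)
    if (nrow(w))
      cand[[i]] <- data.frame(row = w[, 1] + 1L, col = w[, 2] + 1L,
                              sigma_px = sigmas[i],
                              response = core[ismax])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$response), , drop = FALSE]
  # non-maximum suppression at the minimum knob spacing
  keep <- logical(nrow(cand))
  kx <- ky <- numeric(0)
  rad2 <- (suppression_um / pixel_um)^2
  for (j in seq_len(nrow(cand))) {
    if (!length(kx) || all((cand$col[j] - kx)^2 + (cand$row[j] - ky)^2 >= rad2)) {
      keep[j] <- TRUE
      kx <- c(kx, cand$col[j]); ky <- c(ky, cand$row[j])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(x_um = (cand$col - 0.5) * pixel_um,
             y_um = (cand$row - 0.5) * pixel_um,
             sigma_um = cand$sigma_px * pixel_um,
             response = cand$response, row.names = NULL)
}

#' Knob density from sampled counting squares
#'
#' Densities are counts per square scaled to knobs/100 um^2 (a 40 x 40 um
#' square holds 16 of the 100-um^2 reference areas); the estimate is their
#' mean with SEM across squares (SEM is `NA` for a single square).
#'
#' @param counts_per_square integer knob counts, one per sampled square.
#' @param square_um2 sampling-square area in um^2 (default 1600 = 40 x 40).
#' @return list of class `density_estimate`: `density` (knobs/100 um^2),
#'   `sem`, `n_squares`, `per_square`.
#' @export
estimate_density <- function(counts_per_square, square_um2 = 1600) {
  if (!length(counts_per_square)) stop("need at least one square")
  per <- counts_per_square / (square_um2 / 100)
  structure(list(density = mean(per),
                 sem = if (length(per) > 1) stats::sd(per) / sqrt(length(per))
                       else NA_real_,
                 n_squares = length(per), per_square = per),
            class = "density_estimate")
}

#' Pooled knob density across genotype means
#'
#' The density constant used for total-knob normalization is the simple
#' mean of the per-genotype mean densities, rounded half away from zero to
#' `digits` decimals.
#'
#' @param genotype_means numeric vector of per-genotype mean densities
#'   (knobs/100 um^2).
#' @param digits decimals of the reported constant (default 2).
#' @return pooled density in knobs/100 um^2.
#' @export
pooled_density <- function(genotype_means, digits = 2) {
  round_half_away(mean(genotype_means), digits)
}

#' Estimated total knobs in a recorded area
#'
#' `round(density * area / 100)`: converts a recorded area to the knob
#' count against which responder counts are normalized.
#'
#' @param area_um2 recorded area in um^2.
#' @param density knobs per 100 um^2 (default the pooled constant 8.32).
#' @return integer knob count.
#' @export
estimate_total_knobs <- function(area_um2, density = 8.32) {
  if (any(area_um2 < 0)) stop("area must be non-negative")
  as.integer(round_half_away(density * area_um2 / 100))
}

#' Site geometry: recorded area plus its estimated total knob count
#'
#' @param site_id site label.
#' @param area_um2 recorded area in um^2.
#' @param density knobs per 100 um^2.
#' @return data.frame `site_id`, `area_um2`, `estimated_total_knobs`.
#' @export
site_geometry <- function(site_id, area_um2, density = 8.32) {
  if (any(area_um2 <= 0)) stop("recorded area must be positive")
  data.frame(site_id = site_id, area_um2 = area_um2,
             estimated_total_knobs = estimate_total_knobs(area_um2, density))
}
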
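#' Stimulus-selectivity class of a knob
#'
#' Responder flags for the two stimuli of a panel partition every knob into
#' one of four classes: responding only to the first stimulus (`A_only`),
#' only to the second (`B_only`), to both (`both`), or to neither (`none`).
#'
#' @param flag_A,flag_B logical responder flags (vectorized).
#' @return factor with levels `none`, `A_only`, `B_only`, `both`.
#' @export
classify_knob <- function(flag_A, flag_B) {
  if (length(flag_A) != length(flag_B)) stop("flag vectors differ in length")
  cls <- ifelse(flag_A & flag_B, "both",
         ifelse(flag_A, "A_only", ifelse(flag_B, "B_only", "none")))
  factor(cls, levels = c("none", "A_only", "B_only", "both"))
}

#' Per-knob selectivity profiles from responder calls
#'
#' Pivots the per-stimulus responder table of [call_responders()] into one
#' row per knob with its two flags and selectivity class. Stimulus order:
#' `stimuli[1]` is "A", `stimuli[2]` is "B".
#'
#' @param responders data.frame from [call_responders()].
#' @param stimuli length-2 character vector naming the A and B stimuli.
#' @return data.frame `knob_id`, `responds_A`, `responds_B`, `class`.
#' @export
responder_profiles <- function(responders, stimuli) {
  if (length(stimuli) != 2) stop("need exactly two stimuli")
  ids <- unique(responders$knob_id)
  fA <- fB <- logical(length(ids)); names(fA) <- names(fB) <- ids
  a <- responders[responders$stimulus == stimuli[1], ]
  b <- responders[responders$stimulus == stimuli[2], ]
  fA[a$knob_id] <- a$responder
  fB[b$knob_id] <- b$responder
  data.frame(knob_id = ids, responds_A = unname(fA), responds_B = unname(fB),
             class = classify_knob(unname(fA), unname(fB)), row.names = NULL)
}

#' Per-site responder densities as percent of estimated total knobs
#'
#' Class counts divided by the site's estimated total knob count (density x
#' recorded area / 100), expressed in percent.
#'
#' @param profiles data.frame from [responder_profiles()].
#' @param geometry one row of [site_geometry()] for this site.
#' @return data.frame of class `site_summary`: `site_id`,
#'   `estimated_total_knobs`, `n_profiled`, and per class `count_*` and
#'   `density_*` (percent of total knobs) columns.
#' @export
site_summary <- function(profiles, geometry) {
  total <- geometry$estimated_total_knobs[1]
  if (is.na(total) || total <= 0) stop("estimated_total_knobs must be positive")
  if (total < nrow(profiles))
    warning("more profiled knobs (", nrow(profiles),
            ") than estimated total (", total, ")")
  counts <- table(profiles$class)
  out <- data.frame(site_id = geometry$site_id[1],
                    estimated_total_knobs = total,
                    n_profiled = nrow(profiles))
  for (cl in c("A_only", "B_only", "both")) {
    out[[paste0("count_", cl)]] <- as.integer(counts[[cl]])
    out[[paste0("density_", cl)]] <- 100 * counts[[cl]] / total
  }
  class(out) <- c("site_summary", "data.frame")
  out
}

#' Group summary across recording sites
#'
#' Mean and SEM of the per-site class densities, plus the Venn shares of
#' each responder class as percent of all responsive knobs. Shares are
#' reported under both conventions in use for such panels: pooled counts
#' (summed class counts across sites) and mean site densities; the two
#' differ whenever sites differ in size or responder density.
#'
#' @param sites data.frame of stacked [site_summary()] rows.
#' @return list of class `group_summary`: `n_sites`, `density_mean`,
#'   `density_sem` (named by class), `pooled_counts`,
#'   `venn_pooled_counts`, `venn_mean_density` (percent of responsive
#'   knobs), `pooled_responders`.
#' @export
group_summary <- function(sites) {
  if (!nrow(sites)) stop("need at least one site")
  cls <- c("A_only", "B_only", "both")
  dens <- as.matrix(sites[paste0("density_", cls)])
  cnts <- as.matrix(sites[paste0("count_", cls)])
  colnames(dens) <- colnames(cnts) <- cls
  mu <- colMeans(dens)
  sem <- if (nrow(sites) > 1) apply(dens, 2, stats::sd) / sqrt(nrow(sites))
         else rep(NA_real_, 3)
  pooled <- colSums(cnts)
  structure(list(n_sites = nrow(sites),
                 density_mean = mu, density_sem = stats::setNames(sem, cls),
                 pooled_counts = pooled,
                 venn_pooled_counts = 100 * pooled / sum(pooled),
                 venn_mean_density = 100 * mu / sum(mu),
                 pooled_responders = sum(pooled)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary over", x$n_sites, "sites;", x$pooled_responders,
      "responding knobs\n")
  m <- rbind(`density mean (% knobs)` = x$density_mean,
             `density SEM` = x$density_sem,
             `Venn share, pooled counts (%)` = x$venn_pooled_counts,
             `Venn share, mean densities (%)` = x$venn_mean_density)
  print(round(m, 3), ...)
  invisible(x)
}

#' Fold change between a reference and a comparison density
#'
#' `reference / comparison`; a zero comparison with nonzero reference is
#' reported as infinite and flagged.
#'
#' @param reference_density,comparison_density non-negative densities.
#' @return list `fold`, `infinite` (logical flag), `undefined` (both zero).
#' @export
fold_change <- function(reference_density, comparison_density) {
  if (reference_density < 0 || comparison_density < 0)
    stop("densities must be non-negative")
  if (reference_density == 0 && comparison_density == 0)
    return(list(fold = NA_real_, infinite = FALSE, undefined = TRUE))
  if (comparison_density == 0)
    return(list(fold = Inf, infinite = TRUE, undefined = FALSE))
  list(fold = reference_density / comparison_density,
       infinite = FALSE, undefined = FALSE)
}

#' Share of activated knobs responding to a target stimulus
#'
#' Percent of all responsive knobs that respond to the target stimulus,
#' either exclusively (`exclusive = TRUE`) or including the shared class
#' (`exclusive = FALSE`, the default: target-only plus both).
#'
#' @param class_densities named numeric with `A_only`, `B_only`, `both`
#'   (any common unit; shares are scale invariant).
#' @param target `"A"` or `"B"`.
#' @param exclusive count only the target-exclusive class in the numerator.
#' @return percent of activated knobs.
#' @export
activated_share <- function(class_densities, target = c("A", "B"),
                            exclusive = FALSE) {
  target <- match.arg(target)
  d <- class_densities[c("A_only", "B_only", "both")]
  if (any(is.na(d))) stop("class_densities needs A_only, B_only, both")
  tot <- sum(d)
  if (tot == 0) stop("no activated knobs: all class densities are zero")
  num <- d[[paste0(target, "_only")]] + if (exclusive) 0 else d[["both"]]
  100 * num / tot
}
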
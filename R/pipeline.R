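#' Analysis configuration with study defaults
#'
#' Central bundle of the analysis parameters. Defaults are the recording
#' and analysis constants of the study design: 1.5-s frames, 50 baseline
#' frames, threshold at 2 baseline SDs, 60-s latency window, two
#' applications per stimulus, pooled knob-density constant 8.32/100 um^2,
#' strict zero-investigation policy. Any value set away from its default
#' is reported with a message so deviations are visible in logs.
#'
#' @param seed integer seed for generators.
#' @param threshold_mult threshold in multiples of baseline noise SD.
#' @param latency_window_s response latency window after onset (s).
#' @param baseline_frames number of baseline frames.
#' @param frame_interval_s frame interval (s).
#' @param min_run_frames consecutive supra-threshold frames required.
#' @param density knobs per 100 um^2 used for total-knob normalization.
#' @param density_convention `"pooled"` (constant), `"per_site"` or
#'   `"per_genotype"`; which density feeds total-knob estimates.
#' @param rounding_digits decimals for headline shares and folds.
#' @param zero_it_policy `"strict"` or `"epsilon"` for zero investigation
#'   times.
#' @return list of class `run_config` with a `config_hash` attribute.
#' @export
run_config <- function(seed = 1L, threshold_mult = 2, latency_window_s = 60,
                       baseline_frames = 50L, frame_interval_s = 1.5,
                       min_run_frames = 3L, density = 8.32,
                       density_convention = c("pooled", "per_site",
                                              "per_genotype"),
                       rounding_digits = 0L,
                       zero_it_policy = c("strict", "epsilon")) {
  density_convention <- match.arg(density_convention)
  zero_it_policy <- match.arg(zero_it_policy)
  cfg <- list(seed = as.integer(seed), threshold_mult = threshold_mult,
              latency_window_s = latency_window_s,
              baseline_frames = as.integer(baseline_frames),
              frame_interval_s = frame_interval_s,
              min_run_frames = as.integer(min_run_frames),
              density = density, density_convention = density_convention,
              rounding_digits = as.integer(rounding_digits),
              zero_it_policy = zero_it_policy)
  defaults <- list(threshold_mult = 2, latency_window_s = 60,
                   baseline_frames = 50L, frame_interval_s = 1.5,
                   min_run_frames = 3L, density = 8.32,
                   density_convention = "pooled", rounding_digits = 0L,
                   zero_it_policy = "strict")
  for (k in names(defaults))
    if (!identical(cfg[[k]], defaults[[k]]))
      message("config deviates from default: ", k, " = ",
              format(cfg[[k]]), " (default ", format(defaults[[k]]), ")")
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' End-to-end analysis of one recording site
#'
#' Normalizes a site's raw traces, computes baseline statistics, calls
#' per-application responses and per-stimulus responders, classifies
#' selectivity, and summarizes class densities against the site's
#' estimated total knob count.
#'
#' @param dataset a `trace_dataset` (from [generate_trace_dataset()] or
#'   assembled from [read_trace_table()]: list with `traces`, `knobs`,
#'   `protocol`, optional `stimuli`).
#' @param site_id site label.
#' @param density knobs per 100 um^2 for total-knob normalization (default
#'   the pooled constant 8.32; pass a per-site measured value to use the
#'   per-site convention).
#' @param area_um2 recorded area; defaults to the knob field's area
#'   attribute.
#' @param threshold_mult,min_run_frames detection parameters, see
#'   [detect_responses()].
#' @return list of class `site_analysis`: `calls`, `responders`,
#'   `profiles`, `geometry`, `summary` (a [site_summary()]).
#' @export
analyze_site <- function(dataset, site_id = "site1", density = 8.32,
                         area_um2 = NULL, threshold_mult = 2,
                         min_run_frames = 3L) {
  protocol <- dataset$protocol
  stims <- dataset$stimuli %||% unique(protocol$applications$stimulus)
  norm <- normalize_traces(dataset$traces, protocol)
  bs <- baseline_stats(norm, protocol)
  calls <- detect_responses(norm, bs, protocol, threshold_mult,
                            min_run_frames)
  resp <- call_responders(calls, protocol)
  prof <- responder_profiles(resp, stims)
  if (is.null(area_um2)) area_um2 <- attr(dataset$knobs, "area_um2")
  if (is.null(area_um2))
    stop("recorded area unknown: supply `area_um2`")
  geom <- site_geometry(site_id, area_um2, density)
  structure(list(calls = calls, responders = resp, profiles = prof,
                 geometry = geom,
                 summary = site_summary(prof, geom)),
            class = "site_analysis")
}

#' Machine-readable imaging report
#'
#' Collects group summaries (one per experimental group) into a list
#' suitable for JSON serialization, carrying both Venn conventions
#' (pooled counts and mean site densities) explicitly labelled, any
#' between-group tests, and the seed/config hash for provenance.
#'
#' @param groups named list of [group_summary()] objects.
#' @param config a [run_config()].
#' @param tests optional named list of `vnoca_test` results.
#' @param file optional path; when given the report is written as JSON.
#' @return the report list, invisibly when written to `file`.
#' @export
imaging_report <- function(groups, config = run_config(), tests = NULL,
                           file = NULL) {
  rep_group <- function(g) list(
    n_sites = g$n_sites,
    density_mean_pct = as.list(g$density_mean),
    density_sem_pct = as.list(g$density_sem),
    pooled_counts = as.list(g$pooled_counts),
    pooled_responders = g$pooled_responders,
    venn_share_pct = list(
      pooled_counts = as.list(g$venn_pooled_counts),
      mean_site_densities = as.list(g$venn_mean_density)))
  rep <- list(config_hash = attr(config, "config_hash"),
              seed = config$seed,
              density_constant = config$density,
              groups = lapply(groups, rep_group))
  if (!is.null(tests))
    rep$tests <- lapply(tests, function(t)
      list(test = t$test_name, statistic = t$statistic, dof = t$dof,
           p_value = t$p_value, n = t$n))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
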
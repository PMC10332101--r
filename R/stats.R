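#' Two-group comparison with a normality gate
#'
#' The testing policy used throughout the reports: Shapiro-Wilk normality
#' is tested on each group at alpha 0.05; if both pass, an unpaired
#' two-sided Student's t-test (pooled variance) compares the groups,
#' otherwise a two-sided Mann-Whitney (Wilcoxon rank-sum) test is used
#' (exact when sample sizes permit and there are no ties, normal
#' approximation with tie correction otherwise). The chosen test is a pure
#' function of the two samples.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha_normality alpha of the Shapiro-Wilk gate (default 0.05).
#' @return list of class `vnoca_test`: `test_name`, `statistic`, `dof`,
#'   `p_value`, `n` (per group), `normality_p`, `alpha`, `sidedness`.
#' @export
compare_two_groups <- function(x, y, alpha_normality = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 observations")
  # a constant sample has no normality to speak of: fail the gate
  sw <- function(v) if (stats::sd(v) == 0) 0 else
    stats::shapiro.test(v)$p.value
  swx <- sw(x)
  swy <- sw(y)
  if (swx >= alpha_normality && swy >= alpha_normality) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test_name = "unpaired t-test",
                statistic = unname(tt$statistic),
                dof = unname(tt$parameter), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    res <- list(test_name = "Mann-Whitney", statistic = unname(wt$statistic),
                dof = NULL, p_value = wt$p.value)
  }
  structure(c(res, list(n = c(length(x), length(y)),
                        normality_p = c(swx, swy), alpha = 0.05,
                        sidedness = "two-sided")),
            class = "vnoca_test")
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Step-down Sidak: order raw p ascending, adjust `p_(i)` to
#' `1 - (1 - p_(i))^(m - i + 1)`, enforce monotonicity by cumulative
#' maximum, cap at 1. Adjusted values are always >= raw values.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmax(adj, p[o])          # guard floating-point undershoot at k = 1
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m); out[o] <- adj
  out
}

#' Multi-group comparison: Kruskal-Wallis omnibus with adjusted pairwise
#' Mann-Whitney post hoc tests
#'
#' At least three groups are compared with a Kruskal-Wallis rank ANOVA;
#' all pairwise Mann-Whitney tests follow, Holm-Sidak adjusted.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @return list of class `vnoca_multi`: `omnibus` (`vnoca_test`) and
#'   `pairwise` data.frame (`group1`, `group2`, `statistic`, `p_raw`,
#'   `p_adjusted`).
#' @export
compare_multi_groups <- function(groups) {
  if (length(groups) < 3) stop("need at least three groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  omni <- structure(list(test_name = "Kruskal-Wallis",
                         statistic = unname(kw$statistic),
                         dof = unname(kw$parameter), p_value = kw$p.value,
                         n = lengths(groups), alpha = 0.05,
                         sidedness = "two-sided"), class = "vnoca_test")
  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   statistic = NA_real_, p_raw = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pairs[1, j]]],
                                              groups[[pairs[2, j]]]))
    pw$statistic[j] <- unname(wt$statistic)
    pw$p_raw[j] <- wt$p.value
  }
  pw$p_adjusted <- holm_sidak(pw$p_raw)
  structure(list(omnibus = omni, pairwise = pw), class = "vnoca_multi")
}

#' Two-sided one-sample t-test against zero
#'
#' @param x numeric sample (n >= 2, nonzero variance).
#' @return a `vnoca_test` list.
#' @export
one_sample_vs_zero <- function(x) {
  if (length(x) < 2) stop("need at least two observations")
  if (stats::sd(x) == 0)
    stop("zero variance: one-sample t-test is undefined")
  tt <- stats::t.test(x, mu = 0)
  structure(list(test_name = "one-sample t-test",
                 statistic = unname(tt$statistic),
                 dof = unname(tt$parameter), p_value = tt$p.value,
                 n = length(x), alpha = 0.05, sidedness = "two-sided"),
            class = "vnoca_test")
}

#' @export
print.vnoca_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %s)\n", x$test_name,
              x$statistic,
              if (!is.null(x$dof)) sprintf(", df = %.3g", x$dof) else "",
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}
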
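test_that("the selectivity partition is exhaustive and exclusive", {
  got <- classify_knob(c(TRUE, FALSE, TRUE, FALSE),
                       c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(as.character(got), c("A_only", "B_only", "both", "none"))
  expect_error(classify_knob(TRUE, c(TRUE, FALSE)), "length")
})

test_that("site summaries express class counts as percent of total knobs", {
  prof <- data.frame(knob_id = sprintf("k%02d", 1:20),
                     responds_A = c(rep(TRUE, 10), rep(FALSE, 10)),
                     responds_B = c(rep(TRUE, 10), rep(FALSE, 10)))
  prof$class <- classify_knob(prof$responds_A, prof$responds_B)
  geom <- data.frame(site_id = "s1", area_um2 = 12019,
                     estimated_total_knobs = 1000L)
  s <- site_summary(prof, geom)
  expect_equal(s$density_both, 1.0)
  expect_equal(s$count_both, 10L)
  expect_equal(s$density_A_only, 0)
  none <- prof; none$responds_A <- none$responds_B <- FALSE
  none$class <- classify_knob(none$responds_A, none$responds_B)
  s0 <- site_summary(none, geom)
  expect_equal(s0$density_A_only + s0$density_B_only + s0$density_both, 0)
  geom0 <- geom; geom0$estimated_total_knobs <- 0L
  expect_error(site_summary(prof, geom0), "positive")
})

test_that("planted site fractions are recovered within binomial bounds", {
  p <- default_protocol()
  cfg <- synth_config(seed = 13, field_area = c(245, 245))  # ~5000 knobs
  ds <- generate_trace_dataset(generate_knob_field(cfg), p, cfg)
  an <- analyze_site(ds, density = 8.32)
  n <- an$summary$estimated_total_knobs
  for (cl in c("A_only", "B_only", "both")) {
    p0 <- cfg$class_fractions[[cl]]
    got <- an$summary[[paste0("count_", cl)]]
    expect_lt(abs(got - n * p0), 3 * sqrt(n * p0 * (1 - p0)) + 1)
  }
})

test_that("group summaries report both Venn conventions, which sum to 100", {
  mk <- function(id, total, a, b, bo) {
    prof <- data.frame(knob_id = sprintf("%s-%03d", id, 1:(a + b + bo)),
                       responds_A = c(rep(TRUE, a), rep(FALSE, b),
                                      rep(TRUE, bo)),
                       responds_B = c(rep(FALSE, a), rep(TRUE, b),
                                      rep(TRUE, bo)))
    prof$class <- classify_knob(prof$responds_A, prof$responds_B)
    site_summary(prof, data.frame(site_id = id, area_um2 = total * 100 / 8.32,
                                  estimated_total_knobs = total))
  }
  sites <- rbind(mk("s1", 1000, 5, 1, 16), mk("s2", 3000, 15, 3, 40))
  g <- group_summary(sites)
  expect_equal(sum(g$venn_pooled_counts), 100)
  expect_equal(sum(g$venn_mean_density), 100)
  expect_equal(unname(g$pooled_counts), c(20, 4, 56))
  # mean-of-site-densities convention differs from pooled counts when sites
  # differ in size
  expect_false(isTRUE(all.equal(g$venn_pooled_counts, g$venn_mean_density)))
  # shares are invariant to uniform rescaling of densities
  sites2 <- sites
  for (cl in c("A_only", "B_only", "both"))
    sites2[[paste0("density_", cl)]] <- 7 * sites2[[paste0("density_", cl)]]
  expect_equal(group_summary(sites2)$venn_mean_density, g$venn_mean_density)
  one <- mk("s3", 1000, 0, 0, 12)
  g1 <- group_summary(one)
  expect_equal(unname(g1$venn_pooled_counts["both"]), 100)
})

test_that("fold changes handle zero and equal densities", {
  expect_equal(fold_change(0.6, 0.018)$fold, 33.333, tolerance = 1e-3)
  expect_equal(fold_change(0.5, 0.05)$fold, 10)
  expect_equal(fold_change(1.3, 1.3)$fold, 1)
  z <- fold_change(0.4, 0)
  expect_true(z$infinite)
  expect_equal(z$fold, Inf)
  u <- fold_change(0, 0)
  expect_true(u$undefined)
  expect_true(is.na(u$fold))
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("activated shares follow the exclusive/shared definitions", {
  d <- c(A_only = 0.03, B_only = 0.6, both = 0.3)
  expect_equal(activated_share(d, "B"), 100 * 0.9 / 0.93, tolerance = 1e-9)
  expect_equal(activated_share(d, "B", exclusive = TRUE),
               100 * 0.6 / 0.93, tolerance = 1e-9)
  expect_equal(activated_share(c(A_only = 0, B_only = 0.4, both = 0), "B"),
               100)
  expect_error(activated_share(c(A_only = 0, B_only = 0, both = 0), "A"),
               "zero")
})
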
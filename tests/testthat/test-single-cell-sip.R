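# Single-cell SIP: ratio accumulation, QC, LOD, APE and growth rates.

roi1 <- function(c14, c15, group = "Nitrosopumilus",
                 treatment = "NH4_15N") {
  roi_ion_counts("r1", group, treatment, c14, c15)
}

test_that("accumulate_ratio sums over planes and validates", {
  expect_equal(accumulate_ratio(roi1(c(100, 100), c(0, 0))), 0)
  expect_equal(accumulate_ratio(roi1(9963, 37)), 3.7e-3)
  expect_error(accumulate_ratio(roi1(0, 0)), "zero total")
  expect_error(roi_ion_counts("x", "g", "t", c(-1, 2), c(0, 0)),
               "non-negative")
})

test_that("ratio is invariant to plane partitioning", {
  set.seed(42)
  for (i in 1:20) {
    c14 <- rpois(30, 4000); c15 <- rpois(30, 20)
    merged <- roi1(sum(c14), sum(c15))
    split30 <- roi1(c14, c15)
    expect_identical(accumulate_ratio(merged), accumulate_ratio(split30))
  }
})

test_that("poisson_relative_error follows counting statistics", {
  pe <- poisson_relative_error(roi1(1e6, 100))
  expect_equal(pe$rel_error, sqrt(1 / 100 + 1 / 1e6), tolerance = 1e-12)
  expect_false(pe$error_ok)                     # ~10% error fails 5% QC
  pe2 <- poisson_relative_error(roi1(1e6, 2500))
  expect_equal(pe2$rel_error, 0.02, tolerance = 1e-2)
  expect_true(pe2$error_ok)
  # quadrupling both channels halves the error
  expect_equal(poisson_relative_error(roi1(4e6, 400))$rel_error,
               pe$rel_error / 2, tolerance = 1e-12)
  # zero counts in a channel: undefined, QC fail
  pe0 <- poisson_relative_error(roi1(1000, 0))
  expect_true(is.na(pe0$rel_error))
  expect_false(pe0$error_ok)
})

test_that("background window is a closed interval", {
  expect_true(background_qc(3.7e-3))
  expect_false(background_qc(4.1e-3))
  expect_true(background_qc(4.0e-3))
  expect_true(background_qc(3.4e-3))
  expect_false(background_qc(3.39e-3))
  expect_error(background_qc(numeric(0)), "background")
})

test_that("lod_ratio is mean + k * sd of the background", {
  expect_equal(lod_ratio(rep(3.7e-3, 5)), 3.7e-3)
  # two points with mean 3.7e-3 and sd exactly 1e-4
  bg <- 3.7e-3 + c(-1, 1) * 1e-4 / sqrt(2)
  expect_equal(lod_ratio(bg, k = 3), 4.0e-3, tolerance = 1e-12)
  expect_error(lod_ratio(3.7e-3), "background")
})

test_that("atom_percent_excess is affine in the ratio", {
  ctx <- sip_context()
  expect_equal(atom_percent_excess(3.7e-3, ctx), 0)
  expect_equal(atom_percent_excess(3.37e-2, ctx), 3.00)
  expect_equal(atom_percent_excess(3.0e-3, ctx), -0.07)
  expect_error(atom_percent_excess(1.5, ctx), "ratio")
  # affine: equal ratio steps give equal APE steps
  r <- seq(0, 0.05, by = 0.01)
  expect_equal(diff(atom_percent_excess(r, ctx)),
               rep(1, length(r) - 1))
})

test_that("growth_rate is linear in APE and inverse in time", {
  ctx <- sip_context(substrate_at_percent = 97, incubation_time_days = 1)
  expect_equal(growth_rate(0, ctx), 0)
  expect_equal(growth_rate(3, ctx), 3 / (97 - 0.37), tolerance = 1e-12)
  expect_equal(growth_rate(0.13, ctx), 0.13 / 96.63, tolerance = 1e-12)
  expect_equal(growth_rate(6, ctx), 2 * growth_rate(3, ctx))
  ctx2 <- sip_context(substrate_at_percent = 97, incubation_time_days = 2)
  expect_equal(growth_rate(3, ctx2), growth_rate(3, ctx) / 2)
  # negative APE maps to zero
  expect_equal(growth_rate(-0.5, ctx), 0)
  # exponential model agrees closely at small enrichment
  ctxe <- sip_context(growth_model = "exponential")
  expect_equal(growth_rate(3, ctxe), growth_rate(3, ctx), tolerance = 0.02)
  expect_gt(growth_rate(3, ctxe), growth_rate(3, ctx))
})

test_that("cells failing QC are excluded from group summaries", {
  ctx <- sip_context(lod_ratio = 4.0e-3)
  good <- cell_enrichment(roi1(rep(5e4, 30), rep(1000, 30)), ctx)
  expect_true(good$qc_ok)
  # tiny counts: Poisson error way above 5%, however enriched
  bad <- cell_enrichment(roi1(50, 40), ctx)
  expect_false(bad$qc_ok)
  sm <- summarize_group(list(good, bad), ctx)
  expect_equal(sm$n, 1L)
  # background-window failure excludes too
  bad_bg <- cell_enrichment(roi1(rep(5e4, 30), rep(1000, 30)), ctx,
                            background_ratios = rep(5e-3, 4))
  expect_false(bad_bg$qc_ok)
  expect_error(summarize_group(list(bad, bad_bg), ctx), "failed QC")
})

test_that("summaries count cells above per-group detection limits", {
  # synthetic stand-in for a processed single-cell table: 18 cells with one
  # below the ammonium LOD of 4.06e-3
  lods <- data.frame(group = "Nitrosopumilus", treatment = "NH4_15N",
                     lod_ratio = 4.06e-3)
  ctx <- sip_context(lod_ratio = lods)
  ratios <- c(3.9e-3, seq(0.01, 0.042, by = 0.002))
  stopifnot(length(ratios) == 18)
  cells <- lapply(seq_along(ratios), function(i) {
    tot <- 3e6
    n15 <- round(tot * ratios[i])
    cell_enrichment(roi_ion_counts(sprintf("c%02d", i), "Nitrosopumilus",
                                   "NH4_15N", tot - n15, n15), ctx)
  })
  sm <- summarize_group(cells, ctx)
  expect_equal(sm$n, 18L)
  expect_equal(sm$n_above_lod, 17L)
  # per-cell-mean and mean-of-per-cell growth conventions both reported
  expect_true(all(c("mean_growth_rate", "growth_rate_of_mean_ape") %in%
                    names(sm)))
  expect_equal(sm$mean_growth_rate, sm$growth_rate_of_mean_ape,
               tolerance = 1e-6)  # linear model, no clipped cells
})

test_that("published per-group LOD overrides are honored", {
  p <- system.file("extdata", "published_sip_lods.tsv",
                   package = "nitroniche")
  lods <- read.delim(p)
  ctx <- sip_context(lod_ratio = lods)
  # a cell at ratio 3.9e-3: above the WCA ammonium LOD (3.82e-3) but
  # below the Nitrosopumilus ammonium LOD (4.06e-3)
  mk <- function(group) {
    tot <- 3e6; n15 <- round(tot * 3.9e-3)
    cell_enrichment(roi_ion_counts("c1", group, "NH4_15N", tot - n15, n15),
                    ctx)
  }
  expect_true(mk("Nitrosopelagicus_WCA")$above_lod)
  expect_false(mk("Nitrosopumilus")$above_lod)
  # unknown group/treatment pair: no LOD, detection call undefined
  expect_true(is.na(mk("other")$above_lod))
})

test_that("simulated populations recover APE within Monte-Carlo error", {
  cs <- cell_population_scenario(n_cells = 200, true_ape_mean = 1,
                                 true_ape_sd = 0,
                                 mean_total_counts_per_plane = 5000,
                                 n_planes = 20, n_background_cells = 0,
                                 seed = 21)
  ctx <- sip_context()
  est <- vapply(gen_cells(cs), function(r)
    atom_percent_excess(accumulate_ratio(r), ctx), numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 2 * se + 1e-4)
})
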
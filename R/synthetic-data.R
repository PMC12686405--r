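# Synthetic-data generators: every pipeline input with known ground truth.
#
# Each generator draws from its own seeded stream (derived from the
# scenario seed and a stream name) so adding one generator to a workflow
# never perturbs the draws of another, and identical scenarios always
# produce byte-identical tables.

NATURAL_ABUNDANCE_15N <- 3.7e-3  # 15N/(14N+15N), marine natural abundance

#' Describe a 15N tracer incubation experiment to simulate
#'
#' The stated world is a linear accumulation of 15N product at
#' `true_rate * f_label` where `f_label` is the substrate labeling fraction
#' after tracer addition, with additive Gaussian measurement noise.
#'
#' @param true_rate True gross oxidation rate (nM-N day^-1), >= 0.
#' @param ambient Ambient substrate concentration (nM-N).
#' @param tracer_added Tracer addition (nM-N), > 0.
#' @param tracer_purity Fraction of 15N atoms in the tracer, in (0, 1].
#' @param noise_sd Gaussian measurement noise SD (nM-N), >= 0.
#' @param timepoints Sampling times in hours, strictly increasing, >= 3.
#' @param n_replicates Bottles per scenario.
#' @param seed Integer seed; same seed and scenario give identical tables.
#' @param urea_to_ammonium_leak_rate Optional urea-to-ammonium breakdown
#'   rate (nM-N day^-1); when > 0 a combined 15N-ammonium + nitrite series
#'   is simulated alongside the product series.
#' @return An object of class `incubation_scenario`.
#' @export
incubation_scenario <- function(true_rate = 1, ambient = 50,
                                tracer_added = 500, tracer_purity = 0.98,
                                noise_sd = 0.05,
                                timepoints = c(0, 3, 6, 12, 24),
                                n_replicates = 1L, seed = 1L,
                                urea_to_ammonium_leak_rate = 0) {
  assert_scalar_num(true_rate, "true_rate", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(tracer_purity, "tracer_purity", 0, 1,
                    strict_lower = TRUE)
  assert_scalar_num(tracer_added, "tracer_added", 0, strict_lower = TRUE)
  assert_scalar_num(ambient, "ambient", 0)
  assert_scalar_num(urea_to_ammonium_leak_rate,
                    "urea_to_ammonium_leak_rate", 0)
  if (length(timepoints) < 3L || any(diff(timepoints) <= 0)) {
    stopf("timepoints must be strictly increasing with at least 3 points")
  }
  structure(list(true_rate = true_rate, ambient = ambient,
                 tracer_added = tracer_added, tracer_purity = tracer_purity,
                 noise_sd = noise_sd, timepoints = as.numeric(timepoints),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 urea_to_ammonium_leak_rate = urea_to_ammonium_leak_rate),
            class = "incubation_scenario")
}

#' Simulate 15N incubation time series
#'
#' Generates `n_replicates` bottles: product(t) = true_rate * f_label * t
#' (t in days) plus Normal(0, noise_sd) noise. The in-memory series keep
#' the raw noisy values (isotope-excess measurements can dip below zero
#' near the detection limit, and regressing on clipped values would bias
#' null slopes); [incubation_table()] truncates at zero when writing
#' concentrations and flags the truncation. True parameters travel with
#' the result as `truth`.
#'
#' @param scenario An [incubation_scenario()].
#' @param treatment Treatment label attached to the series.
#' @return A list of [incubation_series()] with attributes `truth` (list
#'   with `true_rate`, `f_label`) and `truncated` (logical matrix).
#' @export
gen_incubation <- function(scenario, treatment = "NH4_15N") {
  stopifnot(inherits(scenario, "incubation_scenario"))
  f <- labeling_fraction(scenario$ambient, scenario$tracer_added,
                         scenario$tracer_purity)
  t_h <- scenario$timepoints
  mu <- scenario$true_rate * f * t_h / 24
  leak <- scenario$urea_to_ammonium_leak_rate
  series <- with_seed(stream_seed(scenario$seed, "incubation"), {
    lapply(seq_len(scenario$n_replicates), function(r) {
      y <- mu + rnorm(length(t_h), 0, scenario$noise_sd)
      comb <- NULL
      if (leak > 0) {
        amm <- leak * f * t_h / 24 + rnorm(length(t_h), 0, scenario$noise_sd)
        comb <- y + amm
      }
      s <- incubation_series(t_h, y, f, treatment = treatment,
                             combined_15N_nM = comb, region = "synthetic",
                             station = "sim", depth_m = 0, replicate = r)
      attr(s, "truncated") <- y < 0
      s
    })
  })
  attr(series, "truth") <- list(true_rate = scenario$true_rate, f_label = f,
                                noise_sd = scenario$noise_sd)
  attr(series, "truncated") <- vapply(series,
                                      function(s) attr(s, "truncated"),
                                      logical(length(t_h)))
  series
}

#' Convert simulated incubation series to a tidy table
#'
#' Concentrations are truncated at zero on the way out (a written
#' concentration cannot be negative) and the truncation is flagged in the
#' `truncated` column.
#'
#' @param series A list of [incubation_series()] as returned by
#'   [gen_incubation()].
#' @return Long-format data frame matching the incubation TSV schema.
#' @export
incubation_table <- function(series) {
  rows <- lapply(series, function(s) {
    data.frame(region = s$region, station = s$station, depth_m = s$depth_m,
               treatment = s$treatment, replicate = s$replicate,
               time_h = s$time_h,
               product_15N_nM = pmax(s$product_15N_nM, 0),
               combined_15N_nM = if (is.null(s$combined_15N_nM)) NA_real_
                                 else pmax(s$combined_15N_nM, 0),
               f_label = s$f_label,
               truncated = s$product_15N_nM < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Describe a single-cell population for NanoSIMS simulation
#'
#' @param n_cells Number of labeled cells.
#' @param true_ape_mean,true_ape_sd Mean and SD of the cells' true 15N
#'   atom-percent excess (negative draws are clipped to 0).
#' @param mean_total_counts_per_plane Expected total N ion counts
#'   (14N + 15N) per acquisition plane, > 0.
#' @param n_planes Acquisition planes per region of interest (20 or 30 in
#'   typical raster settings; any positive value accepted).
#' @param n_background_cells Unlabeled cells at natural abundance.
#' @param seed Integer seed.
#' @return An object of class `cell_population_scenario`.
#' @export
cell_population_scenario <- function(n_cells = 20, true_ape_mean = 1,
                                     true_ape_sd = 0,
                                     mean_total_counts_per_plane = 5000,
                                     n_planes = 30, n_background_cells = 10,
                                     seed = 1L) {
  assert_scalar_num(mean_total_counts_per_plane,
                    "mean_total_counts_per_plane", 0, strict_lower = TRUE)
  assert_scalar_num(n_planes, "n_planes", 1)
  assert_scalar_num(true_ape_sd, "true_ape_sd", 0)
  if (n_cells < 0 || n_background_cells < 0) stopf("cell counts must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 true_ape_mean = true_ape_mean, true_ape_sd = true_ape_sd,
                 mean_total_counts_per_plane = mean_total_counts_per_plane,
                 n_planes = as.integer(n_planes),
                 n_background_cells = as.integer(n_background_cells),
                 seed = as.integer(seed)),
            class = "cell_population_scenario")
}

#' Simulate NanoSIMS region-of-interest ion counts
#'
#' For each cell, the total N count per plane is Poisson with the
#' configured mean and the 15N share is Binomial(total, true ratio), the
#' counting statistics of a secondary-ion detector. Background cells are
#' drawn at the natural-abundance ratio (3.7e-3). Each ROI's true
#' atom-percent excess is recorded as ground truth.
#'
#' @param scenario A [cell_population_scenario()].
#' @param group,treatment Labels attached to the labeled cells (background
#'   cells get group `"background"`).
#' @return List of [roi_ion_counts()]; each element carries a `truth_ape`
#'   attribute, and the list a `truth` data frame.
#' @export
gen_cells <- function(scenario, group = "Nitrosopumilus",
                      treatment = "NH4_15N") {
  stopifnot(inherits(scenario, "cell_population_scenario"))
  with_seed(stream_seed(scenario$seed, "cells"), {
    ape <- if (scenario$n_cells > 0) {
      pmax(rnorm(scenario$n_cells, scenario$true_ape_mean,
                 scenario$true_ape_sd), 0)
    } else numeric(0)
    apes <- c(ape, rep(0, scenario$n_background_cells))
    grp <- c(rep(group, scenario$n_cells),
             rep("background", scenario$n_background_cells))
    rois <- vector("list", length(apes))
    for (i in seq_along(apes)) {
      ratio <- NATURAL_ABUNDANCE_15N + apes[i] / 100
      tot <- rpois(scenario$n_planes, scenario$mean_total_counts_per_plane)
      n15 <- rbinom(scenario$n_planes, tot, ratio)
      rois[[i]] <- roi_ion_counts(
        roi_id = sprintf("roi_%03d", i), group = grp[i],
        treatment = treatment, counts_14N = tot - n15, counts_15N = n15)
      attr(rois[[i]], "truth_ape") <- apes[i]
    }
    attr(rois, "truth") <- data.frame(
      roi_id = sprintf("roi_%03d", seq_along(apes)), group = grp,
      truth_ape = apes, stringsAsFactors = FALSE)
    rois
  })
}

#' Describe a synthetic alignment-hit table
#'
#' True-positive reads get a strong custom-database hit relative to their
#' global-database hit; false-positive reads the reverse. Score and
#' identity distributions are Gaussian with the given location/scale.
#'
#' @param n_true,n_false Read counts of each class.
#' @param true_score,false_score Mean custom-database bitscore per class.
#' @param true_global_ratio,false_global_ratio Mean global/custom score
#'   ratio per class (false hits have a stronger global hit).
#' @param true_identity,false_identity Mean percent identity per class.
#' @param score_sd,identity_sd Spread of scores and identities.
#' @param p_global_missing Probability a read has no global-database hit.
#' @param seed Integer seed.
#' @return An object of class `hit_table_scenario`.
#' @export
hit_table_scenario <- function(n_true = 100, n_false = 100,
                               true_score = 200, false_score = 150,
                               true_global_ratio = 0.8,
                               false_global_ratio = 1.5,
                               true_identity = 96, false_identity = 85,
                               score_sd = 20, identity_sd = 3,
                               p_global_missing = 0, seed = 1L) {
  if (n_true < 0 || n_false < 0) stopf("read counts must be >= 0")
  assert_scalar_num(p_global_missing, "p_global_missing", 0, 1)
  structure(list(n_true = as.integer(n_true), n_false = as.integer(n_false),
                 true_score = true_score, false_score = false_score,
                 true_global_ratio = true_global_ratio,
                 false_global_ratio = false_global_ratio,
                 true_identity = true_identity,
                 false_identity = false_identity, score_sd = score_sd,
                 identity_sd = identity_sd,
                 p_global_missing = p_global_missing,
                 seed = as.integer(seed)),
            class = "hit_table_scenario")
}

#' Simulate best-hit tables for the BLAST-score-ratio classifier
#'
#' @param scenario A [hit_table_scenario()].
#' @return Data frame with one row per read: `read_id`, `custom_score`,
#'   `custom_identity`, `custom_subject`, `global_score` (NA when the read
#'   has no global hit) and the ground-truth `truth_label`
#'   (`"true"`/`"false"`).
#' @export
gen_hits <- function(scenario) {
  stopifnot(inherits(scenario, "hit_table_scenario"))
  with_seed(stream_seed(scenario$seed, "hits"), {
    n <- scenario$n_true + scenario$n_false
    lab <- rep(c("true", "false"), c(scenario$n_true, scenario$n_false))
    mu_s <- ifelse(lab == "true", scenario$true_score, scenario$false_score)
    mu_g <- ifelse(lab == "true", scenario$true_global_ratio,
                   scenario$false_global_ratio)
    mu_i <- ifelse(lab == "true", scenario$true_identity,
                   scenario$false_identity)
    cs <- pmax(rnorm(n, mu_s, scenario$score_sd), 1)
    gs <- pmax(rnorm(n, mu_g * cs, scenario$score_sd), 1)
    gs[runif(n) < scenario$p_global_missing] <- NA_real_
    data.frame(read_id = sprintf("read_%05d", seq_len(max(n, 0))),
               custom_score = cs,
               custom_identity = pmin(pmax(rnorm(n, mu_i,
                                                 scenario$identity_sd), 0),
                                      100),
               custom_subject = sprintf("gene_%03d",
                                        sample.int(20, n, replace = TRUE)),
               global_score = gs, truth_label = lab,
               stringsAsFactors = FALSE)
  })
}

#' Simulate depth-resolved nutrient tables with per-region medians
#'
#' Concentrations are log-normal with the configured median (the median of
#' a log-normal is `exp(meanlog)`) and a multiplicative spread; values
#' below the configured analytical LOD are flagged below-detection.
#'
#' @param regions Named list; each element a list with `median_ammonium`,
#'   `median_urea` (nM-N), optional `sdlog` (default 0.6), `lod_ammonium`,
#'   `lod_urea` (default 0), `n` samples (default 50), `depth_range`
#'   (default `c(0, 150)` m).
#' @param seed Integer seed.
#' @return Data frame matching the nutrient TSV schema: region, station,
#'   depth_m, ammonium_nM_N, ammonium_below_lod, ammonium_lod_nM_N, and
#'   the same trio for urea, plus `truth_median_ammonium` / `truth_median_urea`.
#' @export
gen_nutrients <- function(regions, seed = 1L) {
  rows <- lapply(names(regions), function(rn) {
    cfg <- regions[[rn]]
    sdlog <- cfg$sdlog %||% 0.6
    if (sdlog < 0) stopf("sdlog must be >= 0")
    n <- cfg$n %||% 50L
    dr <- cfg$depth_range %||% c(0, 150)
    lod_a <- cfg$lod_ammonium %||% 0
    lod_u <- cfg$lod_urea %||% 0
    with_seed(stream_seed(seed, paste0("nutrients/", rn)), {
      amm <- rlnorm(n, log(cfg$median_ammonium), sdlog)
      ure <- rlnorm(n, log(cfg$median_urea), sdlog)
      data.frame(region = rn, station = sprintf("st%02d", seq_len(n)),
                 depth_m = round(runif(n, dr[1], dr[2]), 1),
                 ammonium_nM_N = amm, ammonium_below_lod = amm < lod_a,
                 ammonium_lod_nM_N = lod_a,
                 urea_nM_N = ure, urea_below_lod = ure < lod_u,
                 urea_lod_nM_N = lod_u,
                 truth_median_ammonium = cfg$median_ammonium,
                 truth_median_urea = cfg$median_urea,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
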
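# File formats, configuration and end-to-end orchestration.
#
# All tabular I/O is TSV with a header row, UTF-8, '.' decimal separator,
# empty fields for missing values; below-detection values are encoded as
# value-plus-flag columns, never "<x" strings.

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tbl <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  }
  for (cc in intersect(numeric_cols, names(tbl))) {
    v <- suppressWarnings(as.numeric(tbl[[cc]]))
    bad <- which(is.na(v) & !is.na(tbl[[cc]]) & tbl[[cc]] != "")
    if (length(bad)) {
      stopf("%s: column '%s' not numeric at data row(s) %s", path, cc,
            paste(head(bad, 5), collapse = ", "))
    }
    tbl[[cc]] <- v
  }
  tbl
}

#' Write a table as TSV
#'
#' @param tbl Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an incubation time-series TSV
#'
#' Expected columns: `region`, `station`, `depth_m`, `treatment`,
#' `replicate`, `time_h`, `product_15N_nM`, `f_label`; optional
#' `combined_15N_nM`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_incubation_tsv <- function(path) {
  read_tsv_checked(path,
                   c("region", "station", "depth_m", "treatment",
                     "replicate", "time_h", "product_15N_nM", "f_label"),
                   c("depth_m", "time_h", "product_15N_nM",
                     "combined_15N_nM", "f_label"))
}

#' Read a nutrient profile TSV
#'
#' Expected columns: `region`, `station`, `depth_m`, `ammonium_nM_N`,
#' `ammonium_below_lod`, `ammonium_lod_nM_N`, `urea_nM_N`,
#' `urea_below_lod`, `urea_lod_nM_N`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_nutrient_tsv <- function(path) {
  tbl <- read_tsv_checked(path,
                          c("region", "station", "depth_m", "ammonium_nM_N",
                            "urea_nM_N"),
                          c("depth_m", "ammonium_nM_N", "ammonium_lod_nM_N",
                            "urea_nM_N", "urea_lod_nM_N"))
  for (fl in c("ammonium_below_lod", "urea_below_lod")) {
    if (!fl %in% names(tbl)) tbl[[fl]] <- FALSE
    tbl[[fl]] <- as.logical(tbl[[fl]])
  }
  tbl
}

#' Read a NanoSIMS ROI ion-count TSV
#'
#' Expected columns: `roi_id`, `group`, `treatment`, `plane`,
#' `counts_14N`, `counts_15N` (one row per plane).
#'
#' @param path Path to the TSV.
#' @return A list of [roi_ion_counts()], one per ROI.
#' @export
read_roi_tsv <- function(path) {
  tbl <- read_tsv_checked(path,
                          c("roi_id", "group", "treatment", "plane",
                            "counts_14N", "counts_15N"),
                          c("plane", "counts_14N", "counts_15N"))
  lapply(split(tbl, tbl$roi_id), function(d) {
    d <- d[order(d$plane), ]
    roi_ion_counts(d$roi_id[1], d$group[1], d$treatment[1], d$counts_14N,
                   d$counts_15N)
  })
}

#' Convert a list of ROIs to the long-format ROI table
#'
#' @param rois List of [roi_ion_counts()].
#' @return Data frame with one row per plane.
#' @export
roi_table <- function(rois) {
  out <- do.call(rbind, lapply(rois, function(r) {
    data.frame(roi_id = r$roi_id, group = r$group, treatment = r$treatment,
               plane = seq_len(r$n_planes), counts_14N = r$counts_14N,
               counts_15N = r$counts_15N, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the 12 standard columns: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore. A row
#' with a different column count is a schema error reported with its line
#' number.
#'
#' @param path Path to the headerless tab-separated file.
#' @return Data frame with the 12 standard columns, typed.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad)) {
    stopf("%s: expected 12 tab-separated columns, found %d at line %d",
          path, nf[bad[1]], bad[1])
  }
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cc in num) out[[cc]] <- as.numeric(out[[cc]])
  out
}

#' Read gene metadata TSV
#'
#' Expected columns: `gene_id`, `family`, `taxon_group`, `length_bp`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_gene_metadata <- function(path) {
  tbl <- read_tsv_checked(path,
                          c("gene_id", "family", "taxon_group", "length_bp"),
                          "length_bp")
  if (any(tbl$length_bp <= 0)) stopf("%s: non-positive gene length", path)
  tbl
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; handles wrapped
#' lines.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

run_config_schema <- function() {
  list(
    seed = "integer",
    output_dir = "character",
    incubation = c("true_rate", "ambient", "tracer_added", "tracer_purity",
                   "noise_sd", "timepoints", "n_replicates",
                   "urea_to_ammonium_leak_rate"),
    rate_policy = "character",
    cells = c("n_cells", "true_ape_mean", "true_ape_sd",
              "mean_total_counts_per_plane", "n_planes",
              "n_background_cells"),
    sip = c("natural_abundance_ratio", "substrate_at_percent",
            "incubation_time_days", "growth_model"),
    hits = c("n_true", "n_false", "true_score", "false_score",
             "true_global_ratio", "false_global_ratio", "true_identity",
             "false_identity", "score_sd", "identity_sd",
             "p_global_missing"),
    classifier = c("min_score", "min_identity", "min_bsr",
                   "missing_global"),
    nutrients = NULL,  # named list of region blocks, free-form region names
    whisker_mode = "character",
    lod_policy = "character"
  )
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML file path or an already-parsed list. Unknown top-level
#' keys (and unknown keys inside known blocks) are rejected by name, so a
#' typo cannot silently fall back to a default.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `run_config` with defaults
#'   filled in and a `config_hash` attribute.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  schema <- run_config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (blk in c("incubation", "cells", "sip", "hits", "classifier")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), schema[[blk]])
      if (length(bad)) {
        stopf("unknown key(s) in '%s': %s", blk, paste(bad, collapse = ", "))
      }
    }
  }
  defaults <- list(
    seed = 1L, output_dir = ".",
    incubation = list(true_rate = 1, ambient = 50, tracer_added = 500,
                      tracer_purity = 0.98, noise_sd = 0.05,
                      timepoints = c(0, 3, 6, 12, 24), n_replicates = 2L,
                      urea_to_ammonium_leak_rate = 0),
    rate_policy = "reconcile_duplicates",
    cells = list(n_cells = 20L, true_ape_mean = 1, true_ape_sd = 0.2,
                 mean_total_counts_per_plane = 5000, n_planes = 30L,
                 n_background_cells = 10L),
    sip = list(natural_abundance_ratio = 3.7e-3, substrate_at_percent = 97,
               incubation_time_days = 1, growth_model = "linear"),
    hits = list(n_true = 100L, n_false = 100L, true_score = 200,
                false_score = 150, true_global_ratio = 0.8,
                false_global_ratio = 1.5, true_identity = 96,
                false_identity = 85, score_sd = 20, identity_sd = 3,
                p_global_missing = 0),
    classifier = list(min_score = 100, min_identity = 90, min_bsr = 0.9,
                      missing_global = "accept"),
    nutrients = list(
      coastal = list(median_ammonium = 320, median_urea = 138,
                     lod_ammonium = 10, lod_urea = 25, n = 50),
      mesotrophic = list(median_ammonium = 51, median_urea = 130,
                         lod_ammonium = 42.7, lod_urea = 27.6, n = 50),
      oligotrophic = list(median_ammonium = 11, median_urea = 52,
                          lod_ammonium = 1, lod_urea = 40, n = 50)),
    whisker_mode = "pct10_90", lod_policy = "lod")
  out <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]) &&
        k != "nutrients") {
      out[[k]][names(config[[k]])] <- config[[k]]
    } else {
      out[[k]] <- config[[k]]
    }
  }
  out$seed <- as.integer(out$seed)
  if (!out$rate_policy %in% c("reconcile_duplicates", "censor_lod",
                              "censor_zero")) {
    stopf("unknown rate_policy '%s'", out$rate_policy)
  }
  if (!out$whisker_mode %in% c("pct10_90", "iqr1_5")) {
    stopf("unknown whisker_mode '%s'", out$whisker_mode)
  }
  # output paths do not affect any computed number, so the provenance hash
  # excludes them: identical analyses hash identically wherever they land
  attr(out, "config_hash") <- config_hash(out[setdiff(names(out),
                                                      "output_dir")])
  class(out) <- "run_config"
  out
}

#' Run the full synthetic pipeline: simulate, rates, SIP, genes, stats
#'
#' Simulates all inputs from the configured scenarios, runs each analysis
#' stage, and writes five output tables (`rates.tsv`, `sip_summary.tsv`,
#' `rpkm.tsv`, `gene_ratios.tsv`, `stats.tsv`) plus a JSON run report to
#' `config$output_dir`. All tables are first built in memory and written
#' only after every stage has succeeded, so partial outputs are never left
#' behind. Outputs are deterministic given the config (all randomness
#' flows from `config$seed`), and every table carries `stage` and
#' `config_hash` provenance columns.
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @return The run report, invisibly: per-stage row counts, QC exclusions,
#'   package version and config hash.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  hash <- attr(config, "config_hash")
  seed <- config$seed
  exclusions <- list()

  # -- simulate + rates ----------------------------------------------------
  inc_amm <- gen_incubation(
    do.call(incubation_scenario,
            c(config$incubation, list(seed = stream_seed(seed, "amm")))),
    treatment = "NH4_15N")
  inc_urea <- gen_incubation(
    do.call(incubation_scenario,
            c(config$incubation, list(seed = stream_seed(seed, "urea")))),
    treatment = "UREA_15N")
  inc_tbl <- rbind(incubation_table(inc_amm), incubation_table(inc_urea))
  rates <- estimate_rates(inc_tbl, policy = config$rate_policy)
  rates$stage <- "rates"; rates$config_hash <- hash

  # -- single-cell SIP -----------------------------------------------------
  cells_sc <- do.call(cell_population_scenario,
                      c(config$cells, list(seed = stream_seed(seed, "sip"))))
  rois <- gen_cells(cells_sc)
  is_bg <- vapply(rois, function(r) r$group == "background", logical(1))
  bg_ratios <- vapply(rois[is_bg], accumulate_ratio, numeric(1))
  ctx <- do.call(sip_context, config$sip)
  enr <- lapply(rois[!is_bg], cell_enrichment, ctx = ctx,
                background_ratios = bg_ratios)
  qc_fail <- vapply(enr, function(x) !isTRUE(x$qc_ok), logical(1))
  if (any(qc_fail)) {
    exclusions$sip_qc <- vapply(enr[qc_fail], function(x) x$roi_id,
                                character(1))
  }
  sip_summary <- summarize_group(enr, ctx)
  sip_summary$stage <- "sip"; sip_summary$config_hash <- hash

  # -- gene quantification -------------------------------------------------
  hits_sc <- do.call(hit_table_scenario,
                     c(config$hits, list(seed = stream_seed(seed, "hits"))))
  hits <- gen_hits(hits_sc)
  cls <- bsr_classify(hits, config$classifier$min_score,
                      config$classifier$min_identity,
                      config$classifier$min_bsr,
                      config$classifier$missing_global)
  exclusions$bsr_rejected <- sum(!cls$accepted)
  genes <- data.frame(
    gene_id = sprintf("gene_%03d", 1:20),
    family = rep(c("amoA", "ureC", "dur3", "16S"), each = 5),
    taxon_group = rep(c("Nitrosopumilus", "Nitrosopelagicus_WCA"),
                      length.out = 20),
    length_bp = rep(c(600, 1700, 2100, 1500), each = 5),
    stringsAsFactors = FALSE)
  accepted <- cls[cls$accepted, , drop = FALSE]
  abund <- gene_abundance(
    data.frame(read_id = accepted$read_id, gene_id = accepted$custom_subject,
               stringsAsFactors = FALSE),
    genes, library_size_reads = max(nrow(hits), 1), sample_id = "synthetic")
  abund$stage <- "genes"; abund$config_hash <- hash
  groups <- unique(genes$taxon_group)
  ratio_rows <- do.call(rbind, lapply(groups, function(g) {
    data.frame(taxon_group = g,
               ureC_to_amoA = group_gene_ratio(abund, g, "ureC"),
               dur3_to_amoA = group_gene_ratio(abund, g, "dur3"),
               stringsAsFactors = FALSE)
  }))
  ratio_rows$stage <- "genes"; ratio_rows$config_hash <- hash

  # -- nutrient stats ------------------------------------------------------
  nutr <- gen_nutrients(config$nutrients, seed = stream_seed(seed, "nutr"))
  frac <- urea_fraction(nutr$urea_nM_N, nutr$ammonium_nM_N,
                        nutr$urea_below_lod, nutr$ammonium_below_lod,
                        nutr$urea_lod_nM_N, nutr$ammonium_lod_nM_N,
                        lod_policy = config$lod_policy)
  regs <- unique(nutr$region)
  stat_rows <- list()
  for (i in seq_along(regs)) {
    b <- box_summary(frac[nutr$region == regs[i]], config$whisker_mode)
    m <- mean_with_se(frac[nutr$region == regs[i]])
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      comparison = sprintf("urea_fraction:%s", regs[i]), group1 = regs[i],
      group2 = NA_character_, n1 = m$n, n2 = NA_integer_, W = NA_real_,
      p_value = NA_real_, method = NA_character_, mean = m$mean, se = m$se,
      median = b$median, q25 = b$q25, q75 = b$q75,
      stringsAsFactors = FALSE)
  }
  if (length(regs) >= 2) {
    for (i in seq_len(length(regs) - 1)) {
      for (j in seq((i + 1), length(regs))) {
        mt <- mann_whitney(frac[nutr$region == regs[i]],
                           frac[nutr$region == regs[j]])
        stat_rows[[length(stat_rows) + 1L]] <- data.frame(
          comparison = "urea_fraction", group1 = regs[i], group2 = regs[j],
          n1 = mt$n1, n2 = mt$n2, W = mt$W, p_value = mt$p_value,
          method = mt$method, mean = NA_real_, se = NA_real_,
          median = NA_real_, q25 = NA_real_, q75 = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  stats_tbl <- do.call(rbind, stat_rows)
  stats_tbl$stage <- "stats"; stats_tbl$config_hash <- hash

  # -- write everything at once --------------------------------------------
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(rates = rates, sip_summary = sip_summary, rpkm = abund,
                  gene_ratios = ratio_rows, stats = stats_tbl)
  for (nm in names(outputs)) {
    write_tsv(outputs[[nm]], file.path(config$output_dir,
                                       paste0(nm, ".tsv")))
  }
  report <- list(
    config_hash = hash, seed = seed,
    package_version = as.character(utils::packageVersion("nitroniche")),
    row_counts = lapply(outputs, nrow), exclusions = exclusions)
  jsonlite::write_json(report,
                       file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `rates`, `sip`, `genes`, `stats` (each runs
#' the full deterministic chain and keeps the named stage's outputs) and
#' `report` (full run). Usage:
#' `nitroniche <subcommand> --config config.yaml [--out DIR]`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: nitroniche <simulate|rates|sip|genes|stats|report> [--config FILE] [--out DIR]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  if (!sub %in% c("simulate", "rates", "sip", "genes", "stats", "report")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(1L))
  }
  cfg_path <- NULL; out_dir <- NULL
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (rest[i] == "--config" && i < length(rest)) {
      cfg_path <- rest[i + 1L]; i <- i + 2L
    } else if (rest[i] == "--out" && i < length(rest)) {
      out_dir <- rest[i + 1L]; i <- i + 2L
    } else {
      message("unknown argument: ", rest[i], "\n", usage)
      return(invisible(1L))
    }
  }
  cfg <- run_config(if (is.null(cfg_path)) list() else cfg_path)
  if (!is.null(out_dir)) cfg$output_dir <- out_dir
  report <- run_pipeline(cfg)
  message(sprintf("[%s] wrote outputs to %s (config %s)", sub,
                  cfg$output_dir, report$config_hash))
  invisible(0L)
}
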
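# Marker-gene quantification: BLAST-score-ratio read classification, RPKM
# abundances, taxon-group gene ratios and oligonucleotide probe coverage.

#' Best hit of one read within one database
#'
#' Maximum bitscore; ties broken by higher percent identity, then by
#' lexicographically smallest subject id, so the result is invariant to
#' input row order.
#'
#' @param hits Data frame of hits for a single read with columns
#'   `bitscore`, `pident`, `sseqid` (extra columns preserved).
#' @return The single best-hit row.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) < 1L) stopf("empty hit list")
  ord <- order(-hits$bitscore, -hits$pident, hits$sseqid)
  hits[ord[1], , drop = FALSE]
}

#' Classify reads with the BLAST-score-ratio criterion
#'
#' A read is accepted as a true positive when its best custom-database hit
#' satisfies all three thresholds: bitscore >= `min_score`, percent
#' identity >= `min_identity`, and BLAST score ratio (best custom score /
#' best global score) >= `min_bsr`. The BSR keeps divergent sequences that
#' score poorly everywhere while discarding reads that match the global
#' database much better than the custom one.
#'
#' @param reads Data frame with one row per read: `read_id`,
#'   `custom_score`, `custom_identity`, `global_score` (NA when the read
#'   had no global-database hit). Use [best_hits_by_read()] to reduce raw
#'   hit tables first.
#' @param min_score,min_identity,min_bsr Acceptance thresholds (defaults
#'   100, 90, 0.9).
#' @param missing_global `"accept"` (default): a read with no global hit
#'   has no evidence of belonging elsewhere, so the BSR criterion is
#'   treated as satisfied and acceptance rests on score and identity
#'   alone. `"strict"`: such reads are rejected.
#' @return The input with columns `bsr` (NA when no global hit) and
#'   logical `accepted` appended.
#' @export
bsr_classify <- function(reads, min_score = 100, min_identity = 90,
                         min_bsr = 0.9,
                         missing_global = c("accept", "strict")) {
  missing_global <- match.arg(missing_global)
  need <- c("read_id", "custom_score", "custom_identity", "global_score")
  miss <- setdiff(need, names(reads))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  bsr <- reads$custom_score / reads$global_score
  bsr_ok <- ifelse(is.na(bsr), missing_global == "accept", bsr >= min_bsr)
  reads$bsr <- bsr
  reads$accepted <- reads$custom_score >= min_score &
    reads$custom_identity >= min_identity & bsr_ok
  reads
}

#' Reduce a raw hit table to one best hit per read
#'
#' @param hits Data frame of raw hits (`qseqid`, `sseqid`, `pident`,
#'   `bitscore`, ...), e.g. parsed BLAST tabular output.
#' @return Data frame with one best-hit row per read, in read-id order.
#' @export
best_hits_by_read <- function(hits) {
  out <- do.call(rbind, lapply(split(hits, hits$qseqid), best_hit))
  rownames(out) <- NULL
  out[order(out$qseqid), , drop = FALSE]
}

#' Second-pass lineage reassignment against a subset database
#'
#' Reads already accepted at the family level are re-screened with the
#' same BSR approach against a lineage-restricted subset database: the
#' subset best-hit score takes the role of the custom score and the
#' full-database best-hit score the role of the global score. The fraction
#' of accepted reads that also pass the subset screen estimates the share
#' of the family belonging to that lineage.
#'
#' @param reads Data frame of BSR-accepted reads with `read_id` and
#'   `custom_score` (the full-database best score).
#' @param subset_hits Data frame with `read_id` and `subset_score` (best
#'   subset-database score; reads absent from the table have no subset
#'   hit and are not assigned).
#' @param min_score,min_identity,min_bsr Thresholds for the second pass;
#'   identity is checked only if `subset_identity` is present.
#' @return List with the per-read logical vector `assigned` (aligned to
#'   `reads`) and the scalar `fraction` of reads assigned to the subset.
#' @export
subset_reassign <- function(reads, subset_hits, min_score = 100,
                            min_identity = 90, min_bsr = 0.9) {
  idx <- match(reads$read_id, subset_hits$read_id)
  ss <- subset_hits$subset_score[idx]
  bsr <- ss / reads$custom_score
  ok <- !is.na(ss) & ss >= min_score & bsr >= min_bsr
  if ("subset_identity" %in% names(subset_hits)) {
    si <- subset_hits$subset_identity[idx]
    ok <- ok & !is.na(si) & si >= min_identity
  }
  list(assigned = ok,
       fraction = if (nrow(reads) > 0) mean(ok) else NA_real_)
}

#' Reads per kilobase of gene per million library reads
#'
#' @param count Reads assigned to the gene.
#' @param gene_length_bp Gene length in bp, > 0.
#' @param library_size_reads Total reads in the library, > 0. Whether
#'   paired reads are counted individually or as pairs is the caller's
#'   convention; state it in output metadata.
#' @return `count / ((gene_length_bp / 1e3) * (library_size_reads / 1e6))`.
#' @export
rpkm <- function(count, gene_length_bp, library_size_reads) {
  if (any(gene_length_bp <= 0)) stopf("gene length must be > 0")
  if (any(library_size_reads <= 0)) stopf("library size must be > 0")
  count / ((gene_length_bp / 1e3) * (library_size_reads / 1e6))
}

#' Per-gene RPKM table from accepted read assignments
#'
#' Each accepted read counts once, for its best custom-database subject.
#'
#' @param assignments Data frame of accepted reads with columns `read_id`
#'   and `gene_id` (the best custom-database subject).
#' @param genes Gene metadata with `gene_id`, `family`, `taxon_group`,
#'   `length_bp`.
#' @param library_size_reads Total reads in the library.
#' @param sample_id Sample label for the output.
#' @return Data frame with one row per gene in `genes`: read count and
#'   RPKM (zero for genes with no reads).
#' @export
gene_abundance <- function(assignments, genes, library_size_reads,
                           sample_id = "sample") {
  counts <- table(factor(assignments$gene_id, levels = genes$gene_id))
  data.frame(sample_id = sample_id, gene_id = genes$gene_id,
             family = genes$family, taxon_group = genes$taxon_group,
             length_bp = genes$length_bp,
             count = as.integer(counts),
             rpkm = rpkm(as.numeric(counts), genes$length_bp,
                         library_size_reads),
             stringsAsFactors = FALSE)
}

#' Ratio of summed group RPKM between two gene families
#'
#' Gene-to-marker ratios against a single-copy marker (default `amoA`)
#' estimate what fraction of a population carries the numerator gene,
#' e.g. a `ureC:amoA` ratio near 1 means essentially every cell encodes
#' urease.
#'
#' @param abundance Per-gene abundance table from [gene_abundance()].
#' @param group Taxon group to restrict to.
#' @param numerator_family Gene family in the numerator.
#' @param denominator_family Gene family in the denominator (default
#'   `"amoA"`).
#' @return Summed-RPKM ratio; `NA` when the denominator aggregate is zero.
#' @export
group_gene_ratio <- function(abundance, group, numerator_family,
                             denominator_family = "amoA") {
  sub <- abundance[abundance$taxon_group == group, , drop = FALSE]
  num <- sum(sub$rpkm[sub$family == numerator_family])
  den <- sum(sub$rpkm[sub$family == denominator_family])
  if (den <= 0) return(NA_real_)
  num / den
}

#' Probe coverage of a reference set by perfect reverse-complement match
#'
#' A reference is covered when it contains the reverse complement of the
#' probe as an exact, case-insensitive substring (probes are designed
#' antisense to the rRNA, so their reverse complement appears in the gene
#' sequence). Coverage is the percentage of reference weight covered:
#' uniform weights give sequence-weighted coverage; passing per-reference
#' read counts gives read-weighted coverage. Degenerate bases are not
#' expanded.
#'
#' @param references A named character vector of reference sequences or a
#'   [Biostrings::DNAStringSet].
#' @param probe Probe sequence (length >= 15).
#' @param weights Optional non-negative per-reference weights (e.g. read
#'   counts); default uniform.
#' @return List with `percent`, logical `matched` per reference, and the
#'   searched `target` (the probe's reverse complement).
#' @export
probe_coverage <- function(references, probe, weights = NULL) {
  if (nchar(probe) < 15) stopf("probe length must be >= 15")
  if (inherits(references, "XStringSet")) {
    refs <- as.character(references)
  } else {
    refs <- as.character(references)
  }
  if (length(refs) < 1L) stopf("empty reference set")
  target <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(probe))))
  matched <- vapply(toupper(refs), function(s) grepl(target, s, fixed = TRUE),
                    logical(1), USE.NAMES = FALSE)
  w <- if (is.null(weights)) rep(1, length(refs)) else as.numeric(weights)
  if (length(w) != length(refs) || any(w < 0)) {
    stopf("weights must be non-negative, one per reference")
  }
  if (sum(w) <= 0) stopf("total reference weight is zero")
  list(percent = 100 * sum(w[matched]) / sum(w), matched = matched,
       target = target)
}
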
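# BSR classification, RPKM quantification and probe coverage.

test_that("best_hit applies score, identity and subject-id tie rules", {
  h <- data.frame(qseqid = "r1", sseqid = c("b", "a"), pident = c(90, 80),
                  bitscore = c(150, 200), stringsAsFactors = FALSE)
  expect_equal(best_hit(h)$sseqid, "a")
  tie <- data.frame(qseqid = "r1", sseqid = c("a", "b"),
                    pident = c(93, 95), bitscore = c(200, 200),
                    stringsAsFactors = FALSE)
  expect_equal(best_hit(tie)$pident, 95)
  tie2 <- data.frame(qseqid = "r1", sseqid = c("z", "a"),
                     pident = c(95, 95), bitscore = c(200, 200),
                     stringsAsFactors = FALSE)
  expect_equal(best_hit(tie2)$sseqid, "a")
  expect_equal(best_hit(h[1, ])$sseqid, "b")
  expect_error(best_hit(h[0, ]), "empty")
})

test_that("best-hit selection is invariant to input row order", {
  set.seed(7)
  hits <- data.frame(
    qseqid = sample(sprintf("r%02d", 1:10), 200, replace = TRUE),
    sseqid = sample(letters[1:6], 200, replace = TRUE),
    pident = sample(seq(80, 100, by = 5), 200, replace = TRUE),
    bitscore = sample(seq(50, 250, by = 25), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  a <- best_hits_by_read(hits)
  b <- best_hits_by_read(hits[sample(nrow(hits)), ])
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("bsr_classify enforces all three thresholds", {
  reads <- data.frame(
    read_id = c("a", "b", "c", "d", "e"),
    custom_score = c(200, 99, 200, 200, 200),
    custom_identity = c(95, 95, 95, 85, 95),
    global_score = c(150, 50, 250, 150, NA),
    stringsAsFactors = FALSE)
  cls <- bsr_classify(reads)
  expect_equal(cls$accepted, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cls$bsr[1], 200 / 150, tolerance = 1e-12)
  # strict mode rejects reads without a global hit
  strict <- bsr_classify(reads, missing_global = "strict")
  expect_false(strict$accepted[5])
  expect_error(bsr_classify(reads[, -2]), "missing columns")
})

test_that("classifier equals the brute-force filter on random tables", {
  set.seed(13)
  for (i in 1:20) {
    sc <- hit_table_scenario(n_true = 50, n_false = 50,
                             p_global_missing = 0.1, seed = i)
    reads <- gen_hits(sc)
    cls <- bsr_classify(reads)
    expect_identical(cls$accepted, bsr_oracle(reads))
    strict <- bsr_classify(reads, missing_global = "strict")
    expect_identical(strict$accepted,
                     bsr_oracle(reads, missing_global_ok = FALSE))
  }
})

test_that("precision/recall of a mixed scenario match the exhaustive filter", {
  reads <- gen_hits(hit_table_scenario(n_true = 200, n_false = 200,
                                       seed = 3))
  cls <- bsr_classify(reads)
  acc_oracle <- bsr_oracle(reads)
  prec <- sum(cls$accepted & reads$truth_label == "true") / sum(cls$accepted)
  prec_o <- sum(acc_oracle & reads$truth_label == "true") / sum(acc_oracle)
  expect_identical(prec, prec_o)
  rec <- sum(cls$accepted[reads$truth_label == "true"]) /
    sum(reads$truth_label == "true")
  rec_o <- sum(acc_oracle[reads$truth_label == "true"]) /
    sum(reads$truth_label == "true")
  expect_identical(rec, rec_o)
})

test_that("subset_reassign recounts lineage fractions exactly", {
  reads <- data.frame(read_id = sprintf("r%02d", 1:10),
                      custom_score = rep(200, 10),
                      stringsAsFactors = FALSE)
  all_in <- data.frame(read_id = reads$read_id, subset_score = rep(200, 10))
  expect_equal(subset_reassign(reads, all_in)$fraction, 1.0)
  none <- data.frame(read_id = character(0), subset_score = numeric(0))
  expect_equal(subset_reassign(reads, none)$fraction, 0.0)

  set.seed(31)
  mixed <- data.frame(read_id = sample(reads$read_id, 6),
                      subset_score = c(200, 150, 90, 200, 120, 200))
  res <- subset_reassign(reads, mixed)
  # brute-force recount with the three thresholds
  expected <- vapply(reads$read_id, function(id) {
    j <- match(id, mixed$read_id)
    !is.na(j) && mixed$subset_score[j] >= 100 &&
      mixed$subset_score[j] / 200 >= 0.9
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(res$assigned, expected)
  expect_equal(res$fraction, mean(expected))
})

test_that("rpkm unit case, scaling and additivity", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(500, 1000, 2e6), rpkm(500, 1000, 1e6) / 2)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 500, 0), "library")
})

test_that("gene_abundance counts reads and group ratios aggregate RPKM", {
  genes <- data.frame(
    gene_id = c("amo1", "amo2", "ure1", "dur1"),
    family = c("amoA", "amoA", "ureC", "dur3"),
    taxon_group = rep("Nitrosopelagicus_WCA", 4),
    length_bp = c(600, 600, 1700, 2100), stringsAsFactors = FALSE)
  # read counts chosen so summed ureC and dur3 RPKM are 1.1x summed amoA
  n_amo <- c(60, 40)                        # amoA RPKM: 100/0.6 ... sums
  amo_rpkm <- sum(rpkm(n_amo, 600, 1e6))
  n_ure <- round(1.1 * amo_rpkm * 1.7)      # invert rpkm at library 1e6
  n_dur <- round(1.1 * amo_rpkm * 2.1)
  assignments <- data.frame(
    read_id = sprintf("r%04d", seq_len(sum(n_amo) + n_ure + n_dur)),
    gene_id = rep(c("amo1", "amo2", "ure1", "dur1"),
                  c(n_amo, n_ure, n_dur)), stringsAsFactors = FALSE)
  ab <- gene_abundance(assignments, genes, 1e6)
  expect_equal(sum(ab$count), nrow(assignments))
  # additivity: group aggregate equals the sum of member RPKMs
  expect_equal(sum(ab$rpkm[ab$family == "amoA"]), amo_rpkm)
  expect_equal(group_gene_ratio(ab, "Nitrosopelagicus_WCA", "ureC"), 1.1,
               tolerance = 0.01)
  expect_equal(group_gene_ratio(ab, "Nitrosopelagicus_WCA", "dur3"), 1.1,
               tolerance = 0.01)
  # zero denominator and zero numerator edge cases
  expect_equal(group_gene_ratio(ab[ab$family != "ureC", ],
                                "Nitrosopelagicus_WCA", "ureC"), 0)
  expect_true(is.na(group_gene_ratio(ab, "Nitrosopumilus", "ureC")))
})

test_that("probe_coverage finds exact reverse-complement matches", {
  probe <- "GCTAATACCGGATAG"              # 15-mer
  target <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  set.seed(5)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 30,
                                   replace = TRUE), collapse = "")
  with_site <- vapply(1:19, function(i) paste0(flank(), target, flank()),
                      character(1))
  without <- paste0(flank(), flank())
  refs <- c(with_site, without)
  cov <- probe_coverage(refs, probe)
  expect_equal(cov$percent, 95)
  expect_equal(sum(cov$matched), 19)
  expect_equal(probe_coverage(with_site, probe)$percent, 100)
  expect_equal(probe_coverage(without, probe)$percent, 0)
  # case-insensitive; read weights shift the percentage
  expect_equal(probe_coverage(tolower(refs[1]), probe)$percent, 100)
  wcov <- probe_coverage(refs, probe, weights = c(rep(1, 19), 81))
  expect_equal(wcov$percent, 19)
  expect_error(probe_coverage(refs, "ACGT"), "probe length")
  expect_error(probe_coverage(character(0), probe), "empty")
})
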
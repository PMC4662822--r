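# a hand-built two-exon transcript on a toy genome, used across blocks
toy_tx <- function(seed = 51) {
  set.seed(seed)
  chrom <- random_dna(600)
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  exons <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(101, 301), end = c(200, 450)))
  utr3 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(401, 450))
  tx <- transcript_model("gT", "gT-RA", "chrT", "+", exons, utr3 = utr3)
  spliced <- paste0(substr(chrom, 101, 200), substr(chrom, 301, 450))
  list(genome = genome, tx = tx, spliced = spliced, chrom = chrom)
}

test_that("reads per million matches the worked normalisation", {
  expect_equal(round(rpm(14350, 16691820), 1), 859.7)
  expect_equal(rpm(1, 1e6), 1.0)
  expect_equal(rpm(0, 5e6), 0.0)
  expect_error(rpm(10, 0), "must be > 0")
})

test_that("reads map to spliced transcripts with orientation and junctions", {
  t <- toy_tx()
  sense_exonic <- substr(t$chrom, 120, 146)          # inside exon 1
  antisense <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(t$chrom, 320, 346))))
  junction <- substr(t$spliced, 90, 116)  # spans the exon1/exon2 joint
  utr_read <- substr(t$chrom, 410, 436)   # fully inside the 3'-UTR
  reads <- make_reads(c(sense_exonic, antisense, junction, utr_read),
                      ids = c("s", "a", "j", "u"))
  m <- map_to_transcripts(reads, list(t$tx), t$genome)
  expect_setequal(m$read_id, c("s", "a", "j", "u"))
  expect_equal(m$orientation[m$read_id == "s"], "sense")
  expect_equal(m$tx_start[m$read_id == "s"], 20)
  expect_false(m$junction[m$read_id == "s"])
  expect_equal(m$orientation[m$read_id == "a"], "antisense")
  expect_true(m$junction[m$read_id == "j"])
  expect_true(m$in_utr3[m$read_id == "u"])
  expect_false(m$in_utr3[m$read_id == "s"])
})

test_that("3'-UTR membership requires entire containment", {
  t <- toy_tx(52)
  inside <- substr(t$chrom, 405, 431)
  straddle <- substr(t$chrom, 390, 416)  # crosses the UTR boundary
  outside <- substr(t$chrom, 120, 146)
  reads <- make_reads(c(inside, straddle, outside, inside, inside),
                      ids = c("i1", "x1", "o1", "i2", "i3"))
  m <- map_to_transcripts(reads, list(t$tx), t$genome)
  expect_equal(utr3_fraction(m, reads), 0.6)  # 3 of 5 inside
  expect_false(m$in_utr3[m$read_id == "x1"])
  # without an annotated UTR the fraction is undefined
  no_utr <- transcript_model("gN", "gN-RA", "chrT", "+",
                             t$tx$exons, utr3 = NULL)
  m2 <- map_to_transcripts(reads[1, ], list(no_utr), t$genome)
  expect_true(is.na(utr3_fraction(m2, reads)))
})

test_that("transcript coordinates convert for minus-strand genes", {
  set.seed(53)
  chrom <- random_dna(400)
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  exons <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(51, 201), end = c(150, 300)))
  tx <- transcript_model("gM", "gM-RA", "chrT", "-", exons)
  # transcript starts at the rightmost genomic base
  expect_equal(genomic_to_tx(tx, 300), 1L)
  expect_equal(genomic_to_tx(tx, 201), 100L)
  expect_equal(genomic_to_tx(tx, 150), 101L)
  expect_equal(genomic_to_tx(tx, 51), 200L)
  # a sense read of a minus-strand gene is the reverse complement of
  # the genomic forward sequence
  sense_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 220, 246))))
  m <- map_to_transcripts(make_reads(sense_seq, ids = "s"),
                          list(tx), genome)
  expect_equal(m$orientation, "sense")
  expect_equal(m$tx_start, genomic_to_tx(tx, 246))
})

test_that("gene RPM filtering is strictly greater-than", {
  prof <- data.frame(gene_id = c("a", "b", "c"),
                     rpm_unique = c(0.6, 0.5, 0))
  kept <- filter_genes_by_rpm(prof, 0.5)
  expect_equal(kept$gene_id, "a")
})

test_that("RPM groups use half-open boundaries", {
  g <- rpm_group(c(7, 10, 50, 3, 5, 49.9, 1000, 0))
  expect_equal(as.character(g),
               c("g5_10", "g10_50", "g50plus", "below", "g5_10",
                 "g10_50", "g50plus", "below"))
})

test_that("length profiles separate siRNA and piRNA mass", {
  all21 <- make_reads(vapply(1:4, function(i) random_dna(21),
                             character(1)))
  expect_equal(length_profile(all21)$sirna21, 1.0)
  half <- make_reads(c(random_dna(21), random_dna(27)))
  lp <- length_profile(half)
  expect_equal(lp$sirna21, 0.5)
  expect_equal(lp$pirna24_29, 0.5)
  expect_equal(sum(lp$histogram$count), 2)
})

test_that("TE contamination flags transcripts and removes dual mappers", {
  t <- toy_tx(54)
  r <- vapply(c(110, 130, 150, 320, 340), function(p)
    substr(t$chrom, p, p + 26), character(1))
  reads <- make_reads(r, counts = c(5L, 5L, 5L, 5L, 5L))
  m <- map_to_transcripts(reads, list(t$tx), t$genome)
  total <- 1e6  # so RPM == count
  te_hits_all <- data.frame(read_id = reads$id)
  f1 <- te_contamination_filter(m, reads, te_hits_all, total, 0.5)
  expect_equal(f1$flagged, "gT-RA")
  expect_equal(nrow(f1$cleaned), 0)
  # below-threshold TE RPM: not flagged, dual reads still removed
  te_hits_few <- data.frame(read_id = reads$id[1])
  f2 <- te_contamination_filter(m, reads, te_hits_few, total * 100, 0.5)
  expect_length(f2$flagged, 0)
  expect_equal(nrow(f2$cleaned), 4)
  expect_false(reads$id[1] %in% f2$cleaned$read_id)
  # no TE hits: nothing flagged, nothing removed
  f3 <- te_contamination_filter(m, reads, te_hits_all[0, , drop = FALSE],
                                total, 0.5)
  expect_length(f3$flagged, 0)
  expect_equal(nrow(f3$cleaned), nrow(m))
  # order safety: cleaning then flagging equals flagging then cleaning
  f4 <- te_contamination_filter(f2$cleaned, reads, te_hits_few,
                                total * 100, 0.5)
  expect_equal(f4$cleaned, f2$cleaned)
})

test_that("summed RPM over a read partition reaches one million", {
  set.seed(55)
  counts <- sample(1:50, 20, replace = TRUE)
  total <- sum(counts)
  expect_equal(sum(rpm(counts, total)), 1e6, tolerance = 1e-9)
})

test_that("profiles recover the planted genic composition", {
  d <- default_sim()
  p <- default_pipeline()
  prof <- p$gene_profiles
  expect_setequal(prof$gene_id, d$spec$genes$gene_id)
  # per-gene sense fraction is fixed by the planted read counts
  g <- d$spec$genes
  planted_sense <- g$n_sense / (g$n_sense + g$n_antisense)
  expect_equal(prof$sense_fraction[match(g$gene_id, prof$gene_id)],
               planted_sense, tolerance = 0.02)
  # pooled 3'-UTR fraction approximates the planted weight
  w <- prof$n_reads
  pooled_utr <- sum(prof$utr3_fraction * w) / sum(w)
  expect_lt(abs(pooled_utr - g$utr3_weight[1]), 0.03)
  expect_true(all(prof$rpm_group == "g50plus"))
})
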
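make_te_lib <- function(seqs, classes = "LTR", families = "Gypsy") {
  lib <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(lib)$te_class <- rep_len(classes, length(seqs))
  S4Vectors::mcols(lib)$te_family <- rep_len(families, length(seqs))
  lib
}

mutate_at <- function(seq, positions) {
  for (p in positions) {
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seq, p, p))[1]
  }
  seq
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

test_that("consensus mapping finds hits up to three mismatches only", {
  set.seed(21)
  te <- random_dna(300)
  lib <- make_te_lib(c(TE1 = te))
  r0 <- substr(te, 101, 127)
  r3 <- mutate_at(r0, c(2, 10, 20))
  r4 <- mutate_at(r0, c(2, 10, 20, 25))
  reads <- make_reads(c(r0, r3, r4), ids = c("r0", "r3", "r4"))
  hits <- consensus_map(reads, lib)
  expect_setequal(hits$read_id, c("r0", "r3"))
  expect_equal(hits$n_mismatches[hits$read_id == "r0"], 0L)
  expect_equal(hits$offset[hits$read_id == "r0"], 101L)
  expect_equal(hits$n_mismatches[hits$read_id == "r3"], 3L)
  expect_true(all(hits$orientation == "sense"))
  expect_true(all(hits$method == "consensus"))
})

test_that("reverse-complement reads map antisense to the consensus", {
  set.seed(22)
  te <- random_dna(300)
  lib <- make_te_lib(c(TE1 = te))
  anti <- revcomp_chr(substr(te, 51, 77))
  hits <- consensus_map(make_reads(anti, ids = "a"), lib)
  expect_equal(hits$orientation, "antisense")
  expect_equal(hits$n_mismatches, 0L)
  expect_equal(hits$offset, 51L)
})

test_that("consensus mapping agrees with the exhaustive Hamming oracle", {
  set.seed(23)
  lib <- make_te_lib(c(TEa = random_dna(150), TEb = random_dna(200)),
                     classes = c("LTR", "DNA"),
                     families = c("Gypsy", "Mariner"))
  reads <- list()
  for (i in 1:25) {
    src <- sample(1:2, 1)
    base <- as.character(lib[[src]])
    L <- sample(24:29, 1)
    off <- sample(nchar(base) - L + 1, 1)
    r <- substr(base, off, off + L - 1)
    nmut <- sample(0:5, 1)
    if (nmut > 0) r <- mutate_at(r, sample(L, nmut))
    if (stats::runif(1) < 0.5) r <- revcomp_chr(r)
    reads[[i]] <- r
  }
  reads <- make_reads(unlist(reads))
  hits <- consensus_map(reads, lib, max_mismatches = 3)
  for (i in seq_len(nrow(reads))) {
    want <- oracle_min_hamming(reads$seq[i], lib)
    h <- hits[hits$read_id == reads$id[i], ]
    if (want <= 3) {
      expect_equal(nrow(h), 1)
      expect_equal(h$n_mismatches, as.integer(want))
    } else {
      expect_equal(nrow(h), 0)
    }
  }
})

test_that("overlap mapping requires exact containment in a masked copy", {
  set.seed(24)
  chrom <- random_dna(2000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  masked <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(501, 900), strand = "+",
    te_name = "TE1", te_class = "LTR", te_family = "Gypsy")
  inside <- substr(chrom, 601, 627)
  mutated <- mutate_at(inside, 5)
  straddle <- substr(chrom, 890, 916)  # half in, half out of the mask
  reads <- make_reads(c(inside, mutated, straddle),
                      ids = c("in", "mut", "straddle"))
  hits <- overlap_map(reads, masked, genome)
  expect_equal(hits$read_id, "in")
  expect_equal(hits$n_mismatches, 0L)
  expect_equal(hits$orientation, "sense")
  expect_equal(hits$method, "overlap")
  expect_error(
    overlap_map(reads, GenomicRanges::shift(masked, 1500), genome),
    "outside genome bounds")
})

test_that("overlap orientation is relative to the masked copy strand", {
  set.seed(25)
  chrom <- random_dna(1000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  minus_copy <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(201, 600), strand = "-",
    te_name = "TE1", te_class = "LTR", te_family = "Gypsy")
  fwd_read <- substr(chrom, 301, 327)        # genome + strand
  rev_read <- revcomp_chr(fwd_read)          # genome - strand
  hits <- overlap_map(make_reads(c(fwd_read, rev_read),
                                 ids = c("fwd", "rev")),
                      minus_copy, genome)
  expect_equal(hits$orientation[hits$read_id == "fwd"], "antisense")
  expect_equal(hits$orientation[hits$read_id == "rev"], "sense")
})

test_that("TE aggregation yields class and family fractions", {
  hits <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    te_name = c(rep("G", 6), rep("C", 3), "M"),
    te_class = c(rep("LTR", 6), rep("LINE", 3), "DNA"),
    te_family = c(rep("Gypsy", 6), rep("CR1", 3), "Mariner"),
    orientation = "sense", offset = 1L, n_mismatches = 0L,
    method = "consensus", stringsAsFactors = FALSE)
  agg <- aggregate_by_te(hits)
  expect_equal(agg$by_class$fraction[agg$by_class$level == "LTR"], 0.6)
  expect_equal(agg$by_class$fraction[agg$by_class$level == "LINE"], 0.3)
  expect_equal(agg$by_class$fraction[agg$by_class$level == "DNA"], 0.1)
  expect_equal(sum(agg$by_family$fraction), 1)
  empty <- aggregate_by_te(hits[0, ])
  expect_equal(nrow(empty$by_class), 0)
  # count weighting shifts the fractions
  reads <- make_reads(rep("ACGT", 10), counts = c(rep(1L, 9), 91L),
                      ids = hits$read_id)
  w <- aggregate_by_te(hits, reads, weight_by_count = TRUE)
  expect_equal(w$by_class$fraction[w$by_class$level == "DNA"], 0.91)
})

test_that("antisense fraction is a simple orientation ratio", {
  hits <- data.frame(read_id = sprintf("r%03d", 1:100),
                     orientation = c(rep("antisense", 69),
                                     rep("sense", 31)))
  expect_equal(antisense_fraction(hits), 0.69)
  expect_equal(antisense_fraction(hits[1:10, ]), 1.0)
  expect_error(antisense_fraction(hits[0, ]), "no TE hits")
})

test_that("genome TE landscape uses base-pair unions", {
  mk <- function(s, e, cls = "LTR", fam = "Gypsy") {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                           te_name = "t", te_class = cls,
                           te_family = fam)
  }
  lens <- c(chr1 = 1000L)
  one <- genome_te_landscape(mk(101, 200), lens)
  expect_equal(one$total, 0.10)
  two <- genome_te_landscape(c(mk(101, 200), mk(151, 250)), lens)
  expect_equal(two$total, 0.15)
  expect_equal(genome_te_landscape(mk(1, 10)[0], lens)$total, 0)
  dom <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 501), c(500, 1000)))
  dom$class <- c("pericentromeric", "euchromatic")
  per_dom <- genome_te_landscape(mk(401, 600), lens, dom)
  expect_equal(
    per_dom$by_domain$fraction[
      per_dom$by_domain$class == "pericentromeric"], 100 / 500)
})

test_that("zero-divergence copies make the two methods agree read-for-read", {
  spec <- sim_spec(seed = 31)
  spec$planted_clusters$n_reads <- c(150L, 100L, 120L)  # clusters unused here
  spec$te_copies$divergence <- 0
  gb <- build_genome(spec)
  sim <- suppressWarnings(simulate_reads(spec, gb))
  te_reads <- sim$reads[sim$reads$id %in%
                          sim$truth$read_id[sim$truth$source == "te"], ]
  ov <- overlap_map(te_reads, gb$masked, gb$genome)
  cm <- consensus_map(te_reads, gb$te_library, max_mismatches = 0)
  expect_setequal(ov$read_id, te_reads$id)
  expect_setequal(cm$read_id, te_reads$id)
  m <- merge(ov, cm, by = "read_id")
  expect_equal(m$te_name.x, m$te_name.y)
  expect_equal(m$orientation.x, m$orientation.y)
})

test_that("consensus hit rate declines with planted copy divergence", {
  rates <- vapply(c(0, 0.05, 0.10), function(d) {
    spec <- sim_spec(seed = 32)
    spec$planted_clusters$n_reads <- c(150L, 100L, 120L)
    spec$te_copies$divergence <- d
    gb <- build_genome(spec)
    sim <- suppressWarnings(simulate_reads(spec, gb))
    te_reads <- sim$reads[sim$reads$id %in%
                            sim$truth$read_id[sim$truth$source == "te"], ]
    nrow(consensus_map(te_reads, gb$te_library)) / nrow(te_reads)
  }, numeric(1))
  expect_equal(rates[1], 1.0)
  expect_gte(rates[1], rates[2])
  expect_gt(rates[2], rates[3])
  # the overlap method is invariant to consensus divergence
  spec <- sim_spec(seed = 32)
  spec$planted_clusters$n_reads <- c(150L, 100L, 120L)
  spec$te_copies$divergence <- 0.10
  gb <- build_genome(spec)
  sim <- suppressWarnings(simulate_reads(spec, gb))
  te_reads <- sim$reads[sim$reads$id %in%
                          sim$truth$read_id[sim$truth$source == "te"], ]
  ov <- overlap_map(te_reads, gb$masked, gb$genome)
  expect_setequal(ov$read_id, te_reads$id)
})
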
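test_that("window binning assigns reads by their 5' end", {
  al <- make_alignments("chr1",
                        start = c(12004, 4999, 100),
                        end = c(12029, 5024, 126),
                        strand = c("+", "-", "+"))
  w <- bin_to_windows(al, window_size = 5000)
  # plus read: 5' end 12004 -> window 2; minus read: 5' end 5024 ->
  # window 1 (its rightmost base); third read -> window 0
  expect_equal(w$index, c(0L, 1L, 2L))
  expect_equal(w$count_plus, c(1L, 0L, 1L))
  expect_equal(w$count_minus, c(0L, 1L, 0L))
  expect_equal(w$start, c(1L, 5001L, 10001L))
  expect_equal(w$end, c(5000L, 10000L, 15000L))
  expect_equal(nrow(bin_to_windows(al[0])), 0)
  expect_error(bin_to_windows(al, 5000, chrom_lengths = c(chr1 = 10000)),
               "beyond declared")
})

test_that("minimum cluster totals reproduce the printed thresholds", {
  expect_identical(min_total_threshold(568080), 284L)
  expect_identical(min_total_threshold(202533), 101L)
  expect_identical(min_total_threshold(0), 0L)
  expect_error(min_total_threshold(-5))
})

make_windows <- function(counts, chrom = "chr1", W = 5000L) {
  idx <- which(counts > 0) - 1L
  data.frame(chrom = chrom, index = idx,
             start = idx * W + 1L, end = (idx + 1L) * W,
             count_plus = counts[counts > 0], count_minus = 0L)
}

test_that("gap rule joins runs across up to four sub-threshold windows", {
  # qualifying windows at indices 0 and 5: gap of 4 -> one cluster
  counts <- c(20, 1, 1, 1, 1, 20)
  cl <- call_clusters(make_windows(counts), 10, 4, 0)
  expect_length(cl, 1)
  expect_equal(GenomicRanges::start(cl), 1)
  expect_equal(GenomicRanges::end(cl), 30000)
  expect_equal(cl$n_unique_pirnas, 44L)  # gap windows count in the total

  # gap of 5 -> two clusters, each tested against min_total separately
  counts2 <- c(20, 1, 1, 1, 1, 1, 20)
  cl2 <- call_clusters(make_windows(counts2), 10, 4, 0)
  expect_length(cl2, 2)
  expect_equal(GenomicRanges::start(cl2), c(1, 30001))
  cl2b <- call_clusters(make_windows(counts2), 10, 4, 21)
  expect_length(cl2b, 0)

  # all below threshold -> no clusters
  expect_length(call_clusters(make_windows(c(5, 9, 3)), 10, 4, 0), 0)
})

test_that("cluster spans are trimmed to qualifying windows", {
  counts <- c(3, 15, 2, 15, 4)
  cl <- call_clusters(make_windows(counts), 10, 4, 0)
  expect_length(cl, 1)
  expect_equal(GenomicRanges::start(cl), 5001)   # window 1
  expect_equal(GenomicRanges::end(cl), 20000)    # end of window 3
})

test_that("cluster calling matches brute-force enumeration", {
  set.seed(11)
  for (case in 1:120) {
    n <- sample(5:60, 1)
    counts <- ifelse(stats::runif(n) < 0.3,
                     sample(10:40, n, replace = TRUE),
                     sample(0:9, n, replace = TRUE))
    mpw <- sample(5:15, 1)
    gap <- sample(0:5, 1)
    mt <- sample(c(0, 10, 30, 60), 1)
    got <- call_clusters(make_windows(counts, W = 5000L), mpw, gap, mt)
    want <- oracle_clusters(counts, mpw, gap, mt)
    expect_equal(length(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(GenomicRanges::start(got), want$first * 5000 + 1)
      expect_equal(GenomicRanges::end(got), (want$last + 1) * 5000)
      expect_equal(got$n_unique_pirnas, want$total)
    }
  }
})

test_that("cluster calling invariants hold on random landscapes", {
  set.seed(12)
  for (case in 1:25) {
    n <- sample(20:120, 1)
    counts <- ifelse(stats::runif(n) < 0.25,
                     sample(10:40, n, replace = TRUE),
                     sample(0:9, n, replace = TRUE))
    w <- make_windows(counts)
    base <- call_clusters(w, 10, 2, 0)
    # every qualifying window lies inside some candidate cluster
    qual <- which(counts >= 10) - 1L
    if (length(qual) > 0 && length(base) > 0) {
      pos <- qual * 5000 + 2500
      inside <- vapply(pos, function(p)
        any(GenomicRanges::start(base) <= p &
              GenomicRanges::end(base) >= p), logical(1))
      expect_true(all(inside))
    }
    # clusters pairwise disjoint and sorted
    if (length(base) > 1) {
      expect_true(all(GenomicRanges::start(base)[-1] >
                        GenomicRanges::end(base)[-length(base)]))
    }
    # raising min_total never increases the number of clusters
    expect_lte(length(call_clusters(w, 10, 2, 50)), length(base))
    # raising max_gap_windows never increases it (runs can only merge)
    expect_lte(length(call_clusters(w, 10, 4, 0)), length(base))
  }
})

test_that("strand bias classes use strict 75/90 percent thresholds", {
  mk <- function(p, m) {
    cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
    cl$n_unique_pirnas <- p + m
    cl$count_plus <- p
    cl$count_minus <- m
    classify_strand_bias(cl)
  }
  a <- mk(76L, 24L)
  expect_equal(a$dominant_fraction, 0.76)
  expect_equal(a$bias_class, "strong")
  expect_equal(a$dominant_strand, "+")
  b <- mk(9L, 91L)
  expect_equal(b$bias_class, "near_exclusive")
  expect_equal(b$dominant_strand, "-")
  c3 <- mk(50L, 50L)
  expect_equal(c3$bias_class, "unbiased")
  expect_equal(c3$dominant_strand, "none")
  # strictly-greater-than boundaries
  expect_equal(mk(75L, 25L)$bias_class, "unbiased")
  expect_equal(mk(90L, 10L)$bias_class, "strong")
  expect_length(classify_strand_bias(mk(1L, 1L)[0]), 0)
  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  bad$count_plus <- 0L
  bad$count_minus <- 0L
  expect_error(classify_strand_bias(bad), "no piRNAs")
})

test_that("chromatin assignment follows majority overlap with tie priority", {
  dom <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 10001), end = c(10000, 30000)))
  dom$class <- c("pericentromeric", "euchromatic")
  mk_cl <- function(s, e) {
    cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    cl$n_unique_pirnas <- 100L
    cl
  }
  inside <- assign_chromatin(mk_cl(2000, 8000), dom)
  expect_equal(inside$chromatin_class, "pericentromeric")
  # 60 % euchromatic / 40 % pericentromeric by bp -> euchromatic
  split_cl <- assign_chromatin(mk_cl(6001, 16000), dom)
  expect_equal(split_cl$chromatin_class, "euchromatic")
  outside <- assign_chromatin(mk_cl(50001, 60000), dom)
  expect_equal(outside$chromatin_class, "unassigned")
  # exact tie goes to the more heterochromatic class
  tie <- assign_chromatin(mk_cl(5001, 15000), dom)
  expect_equal(tie$chromatin_class, "pericentromeric")
  bad <- dom
  GenomicRanges::end(bad)[1] <- 12000
  expect_error(assign_chromatin(mk_cl(1, 100), bad),
               "overlapping chromatin domains")
})

test_that("cluster TE content is union coverage of masked intervals", {
  cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  cl$n_unique_pirnas <- 100L
  mk_mask <- function(s, e) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                           te_name = "t", te_class = "LTR",
                           te_family = "Gypsy")
  }
  full <- cluster_te_content(cl, mk_mask(1, 10000))
  expect_equal(full$te_content, 1.0)
  # overlapping masked copies merge: union [1,3000] = 3 kb of 10 kb
  two <- cluster_te_content(cl, c(mk_mask(1, 2000), mk_mask(1001, 3000)))
  expect_equal(two$te_content, 0.3)
  none <- cluster_te_content(cl, mk_mask(90001, 95000))
  expect_equal(none$te_content, 0)
  # random-interval oracle
  set.seed(13)
  for (case in 1:10) {
    s <- sample(1:9000, 5)
    e <- pmin(s + sample(100:2000, 5, replace = TRUE), 10000L)
    m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                te_name = "t", te_class = "LTR",
                                te_family = "Gypsy")
    got <- cluster_te_content(cl, m)$te_content
    expect_equal(got, oracle_union_bp(s, e, 1, 10000) / 10000)
  }
})

test_that("production shares partition unique piRNAs", {
  cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 25000))
  cl$n_unique_pirnas <- 3L
  cl$chromatin_class <- "euchromatic"
  al_in <- make_alignments("chr1", c(6000, 7000, 20000),
                           c(6026, 7026, 20026), "+")
  shares <- production_shares(cl, al_in)
  expect_equal(shares$fraction[shares$class == "euchromatic"], 1)
  expect_equal(sum(shares$fraction), 1)
  empty_cl <- cl[0]
  shares0 <- production_shares(empty_cl, al_in)
  expect_equal(shares0$fraction[shares0$class == "outside_clusters"], 1)
  # a minus-strand read is attributed by its 5' (rightmost) end
  al_edge <- make_alignments("chr1", 4990, 5016, "-")
  sh <- production_shares(cl, al_edge)
  expect_equal(sh$fraction[sh$class == "euchromatic"], 1)
})

test_that("cluster ranking is deterministic under ties", {
  cl <- GenomicRanges::GRanges(
    c("chr2", "chr1", "chr1"),
    IRanges::IRanges(start = c(1, 50001, 1), width = 10000))
  cl$n_unique_pirnas <- c(300L, 500L, 284L)
  r <- rank_clusters(cl)
  expect_equal(r$n_unique_pirnas, c(500L, 300L, 284L))
  cl$n_unique_pirnas <- c(300L, 300L, 300L)
  r2 <- rank_clusters(cl)
  expect_equal(as.character(GenomicRanges::seqnames(r2)),
               c("chr1", "chr1", "chr2"))
  expect_equal(GenomicRanges::start(r2), c(1, 50001, 1))
  expect_length(rank_clusters(cl, top_n = 2), 2)
  expect_length(rank_clusters(cl, top_n = 10), 3)
})
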
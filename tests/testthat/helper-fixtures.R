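# Shared fixtures and independent oracles for the test suite.
# The default simulated landscape is computed once per session and reused.

.fixture_cache <- new.env(parent = emptyenv())

# default synthetic landscape (the package's reference study conditions)
default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    spec <- sim_spec(seed = 1)
    gb <- build_genome(spec)
    sim <- suppressWarnings(simulate_reads(spec, gb))
    .fixture_cache$sim <- list(spec = spec, gb = gb, sim = sim)
  }
  .fixture_cache$sim
}

# the full pipeline run on the default landscape, computed once
default_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    d <- default_sim()
    .fixture_cache$pipe <- suppressWarnings(run_pipeline(
      d$sim$reads, d$sim$alignments,
      te_library = d$gb$te_library, masked = d$gb$masked,
      genome = d$gb$genome, transcripts = d$gb$transcripts,
      domains = d$gb$domains, chrom_lengths = d$spec$chrom_lengths))
  }
  .fixture_cache$pipe
}

make_reads <- function(seqs, counts = 1L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, seq = seqs,
             count = rep_len(as.integer(counts), length(seqs)),
             stringsAsFactors = FALSE)
}

make_alignments <- function(chrom, start, end, strand, read_id = NULL,
                            n_genome_hits = 1L) {
  n <- length(start)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = rep_len(strand, n))
  gr$read_id <- read_id
  gr$n_genome_hits <- rep_len(as.integer(n_genome_hits), n)
  gr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- independent oracles -------------------------------------------------

# brute-force cluster caller: enumerate all maximal valid runs directly
# from the rule text. counts is a plain vector over window indices
# 0..length(counts)-1.
oracle_clusters <- function(counts, min_per_window, max_gap_windows,
                            min_total) {
  n <- length(counts)
  qual <- which(counts >= min_per_window) - 1L  # 0-based indices
  if (length(qual) == 0) {
    return(data.frame(first = integer(), last = integer(),
                      total = integer()))
  }
  valid_span <- function(a, b) {
    # every maximal run of sub-threshold windows inside [a, b] has
    # length <= max_gap_windows, and a, b are qualifying
    idx <- seq.int(a, b)
    sub <- counts[idx + 1L] < min_per_window
    if (sub[1] || sub[length(sub)]) return(FALSE)
    r <- rle(sub)
    all(r$lengths[r$values] <= max_gap_windows)
  }
  spans <- list()
  for (a in qual) for (b in qual[qual >= a]) {
    if (valid_span(a, b)) spans[[length(spans) + 1L]] <- c(a, b)
  }
  spans <- do.call(rbind, spans)
  # keep maximal spans only
  keep <- vapply(seq_len(nrow(spans)), function(i) {
    !any(spans[, 1] <= spans[i, 1] & spans[, 2] >= spans[i, 2] &
           (spans[, 1] != spans[i, 1] | spans[, 2] != spans[i, 2]))
  }, logical(1))
  spans <- spans[keep, , drop = FALSE]
  total <- vapply(seq_len(nrow(spans)), function(i)
    sum(counts[(spans[i, 1]:spans[i, 2]) + 1L]), numeric(1))
  ok <- total >= min_total
  out <- data.frame(first = spans[ok, 1], last = spans[ok, 2],
                    total = as.integer(total[ok]))
  out[order(out$first), , drop = FALSE]
}

# exhaustive all-offsets Hamming search over a consensus library
# (both strands); returns the minimum distance found, or Inf
oracle_min_hamming <- function(seq, lib) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                 collapse = ""))
  }
  best <- Inf
  pat <- strsplit(seq, "")[[1]]
  L <- length(pat)
  for (ref in as.character(lib)) {
    for (subject in c(ref, revcomp(ref))) {
      sub <- strsplit(subject, "")[[1]]
      if (length(sub) < L) next
      for (off in seq_len(length(sub) - L + 1L)) {
        d <- sum(pat != sub[off:(off + L - 1L)])
        if (d < best) best <- d
      }
    }
  }
  best
}

# base-pair union of intervals via position marking
oracle_union_bp <- function(starts, ends, lo, hi) {
  covered <- logical(hi - lo + 1L)
  for (i in seq_along(starts)) {
    s <- max(starts[i], lo)
    e <- min(ends[i], hi)
    if (s <= e) covered[(s - lo + 1L):(e - lo + 1L)] <- TRUE
  }
  sum(covered)
}

# brute-force ping-pong pair enumeration (pair weighting, unit counts)
oracle_pingpong_pairs <- function(alignments, k_max) {
  chrom <- as.character(GenomicRanges::seqnames(alignments))
  strand <- as.character(GenomicRanges::strand(alignments))
  pos5 <- ifelse(strand == "-", GenomicRanges::end(alignments),
                 GenomicRanges::start(alignments))
  counts <- stats::setNames(numeric(k_max), seq_len(k_max))
  n <- length(alignments)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (chrom[i] != chrom[j]) next
    if (strand[i] != "+" || strand[j] != "-") next
    k <- pos5[j] - pos5[i] + 1L
    if (k >= 1 && k <= k_max) counts[k] <- counts[k] + 1
  }
  counts
}
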
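#' Simulation specification for a synthetic piRNA landscape
#'
#' Defines a small two-chromosome genome with planted structure mirroring
#' an ovarian small-RNA study: piRNA clusters (uni- and bi-directionally
#' transcribed), transposon copies diverged from their consensus,
#' ping-pong primary/secondary pairs with 10-nt 5' overlaps, genic reads
#' concentrated in 3'-UTRs, 22-nt miRNA contaminants and sparse
#' background. The defaults are the package's reference study conditions:
#' read lengths 24-29 nt with the apex at 27 nt, a 79 % 1U bias, a 54 %
#' sense 10A bias, strand-bias mixes covering the near-exclusive
#' (>90 %), strong (>75 %) and unbiased cluster classes, and a TE read
#' composition giving ~69 % antisense piRNAs.
#'
#' Identical `seed` and parameters give byte-identical outputs.
#'
#' @param seed integer seed driving a single pseudo-random stream
#'   (R's default Mersenne-Twister).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window_size cluster-calling window width the planted intervals
#'   are aligned to (default 5000).
#' @param planted_clusters data.frame: `chrom`, `start`, `end`
#'   (window-aligned), `n_reads`, `strand_bias` (dominant-strand
#'   probability in `[0.5, 1]`), `directionality` (`uni`/`bi`),
#'   `dominant_strand`.
#' @param te_copies data.frame: `consensus` (one of `AgGypsy1`, `AgCR1`,
#'   `AgMar1`), `chrom`, `start`, `divergence` (per-base substitution
#'   rate of the planted copy), `strand`, `n_primary` (antisense reads),
#'   `n_sense` (independent sense reads). Secondaries are spawned from
#'   primaries at `pingpong_fraction`.
#' @param genes data.frame of two-exon (or single-exon) gene models:
#'   `gene_id`, `chrom`, `strand`, `exon1_start`, `exon1_end`,
#'   `exon2_start`, `exon2_end` (NA for single-exon), `utr3_start`,
#'   `utr3_end`, `n_sense`, `n_antisense`, `utr3_weight`.
#' @param pingpong_fraction probability that a primary spawns a secondary
#'   partner on the opposite strand at an exact 10-nt 5' overlap.
#' @param u1_bias probability of a 5' U on cluster reads and TE primary
#'   (antisense) reads.
#' @param a10_bias probability of a position-10 A on independent sense TE
#'   reads.
#' @param length_probs named probability vector over piRNA read lengths.
#' @param n_hotspots_primary,n_hotspots_sense distinct 5'-end hotspots
#'   per TE copy (read multiplicity concentrates on hotspots, as in real
#'   libraries).
#' @param n_gene_hotspots_sense,n_gene_hotspots_antisense distinct
#'   hotspots per gene.
#' @param mirna_n,mirna_loci total 22-nt miRNA reads and number of loci.
#' @param background_per_window mean background reads per window (far
#'   below the 10-per-window cluster threshold).
#' @param chromatin_domains data.frame `chrom`, `start`, `end`, `class`.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 250000L, chr2 = 200000L),
    window_size = 5000L,
    planted_clusters = data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      start = c(25001L, 150001L, 30001L),
      end = c(55000L, 175000L, 60000L),
      n_reads = c(1500L, 1000L, 1200L),
      strand_bias = c(0.95, 0.55, 0.85),
      directionality = c("uni", "bi", "uni"),
      dominant_strand = c("+", "+", "+"),
      stringsAsFactors = FALSE),
    te_copies = data.frame(
      consensus = c("AgGypsy1", "AgCR1", "AgMar1", "AgGypsy1", "AgCR1",
                    "AgMar1"),
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
      start = c(30001L, 155001L, 165001L, 40001L, 120001L, 145001L),
      divergence = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
      strand = c("-", "-", "-", "-", "+", "+"),
      n_primary = c(150L, 150L, 150L, 150L, 0L, 0L),
      n_sense = c(22L, 22L, 22L, 22L, 0L, 0L),
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene_id = c("g1", "g2", "g3"),
      chrom = c("chr2", "chr1", "chr2"),
      strand = c("+", "-", "+"),
      exon1_start = c(80001L, 220001L, 170001L),
      exon1_end = c(80600L, 220700L, 171200L),
      exon2_start = c(80901L, 221001L, NA),
      exon2_end = c(81500L, 221500L, NA),
      utr3_start = c(81101L, 220001L, 170901L),
      utr3_end = c(81500L, 220400L, 171200L),
      n_sense = c(330L, 330L, 330L),
      n_antisense = c(70L, 70L, 70L),
      utr3_weight = c(0.58, 0.58, 0.58),
      stringsAsFactors = FALSE),
    pingpong_fraction = 0.30,
    u1_bias = 0.79,
    a10_bias = 0.54,
    length_probs = c(`24` = 0.08, `25` = 0.15, `26` = 0.20, `27` = 0.30,
                     `28` = 0.17, `29` = 0.10),
    n_hotspots_primary = 8L,
    n_hotspots_sense = 4L,
    n_gene_hotspots_sense = 4L,
    n_gene_hotspots_antisense = 2L,
    mirna_n = 300L,
    mirna_loci = 5L,
    background_per_window = 0.2,
    chromatin_domains = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
      start = c(1L, 100001L, 200001L, 1L, 140001L, 160001L),
      end = c(100000L, 200000L, 250000L, 140000L, 160000L, 200000L),
      class = c("pericentromeric", "intercalary_diffuse", "euchromatic",
                "euchromatic", "intercalary_compact", "euchromatic"),
      stringsAsFactors = FALSE)) {
  stopifnot(abs(sum(length_probs) - 1) < 1e-9,
            all(planted_clusters$strand_bias >= 0.5),
            all(planted_clusters$strand_bias <= 1),
            pingpong_fraction >= 0, pingpong_fraction <= 1,
            all(planted_clusters$end <= chrom_lengths[
              planted_clusters$chrom]))
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    window_size = as.integer(window_size),
    planted_clusters = planted_clusters, te_copies = te_copies,
    genes = genes, pingpong_fraction = pingpong_fraction,
    u1_bias = u1_bias, a10_bias = a10_bias,
    length_probs = length_probs,
    n_hotspots_primary = as.integer(n_hotspots_primary),
    n_hotspots_sense = as.integer(n_hotspots_sense),
    n_gene_hotspots_sense = as.integer(n_gene_hotspots_sense),
    n_gene_hotspots_antisense = as.integer(n_gene_hotspots_antisense),
    mirna_n = as.integer(mirna_n), mirna_loci = as.integer(mirna_loci),
    background_per_window = background_per_window,
    chromatin_domains = chromatin_domains), class = "sim_spec")
}

.te_consensus_defs <- data.frame(
  name = c("AgGypsy1", "AgCR1", "AgMar1"),
  te_class = c("LTR", "LINE", "DNA"),
  te_family = c("Gypsy", "CR1", "Mariner"),
  length = c(1200L, 1000L, 800L),
  stringsAsFactors = FALSE)

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < divergence
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Build the synthetic genome and its annotation truth
#'
#' Generates a uniform-random background sequence per chromosome, a TE
#' consensus library (one LTR/Gypsy, one LINE/CR1, one DNA/Mariner
#' element), writes each planted TE copy into the genome after mutating
#' the consensus at the copy's divergence (reverse-complemented for
#' minus-strand copies), and lays out gene models and miRNA loci on the
#' background. Planted TE copies, genes and miRNA loci must not overlap
#' one another (clusters may and do contain TE copies).
#'
#' @param spec a [sim_spec()].
#' @return list with `genome` (`DNAStringSet`), `te_library`
#'   (consensus `DNAStringSet` with `te_class`/`te_family` metadata),
#'   `masked` (TE-copy truth `GRanges`), `transcripts` (list of
#'   [transcript_model]s), `mirna_loci` (`GRanges`), `domains`
#'   (`GRanges`) and `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  chroms <- lapply(spec$chrom_lengths, .random_dna)
  defs <- .te_consensus_defs
  cons <- stats::setNames(
    vapply(defs$length, .random_dna, character(1)), defs$name)
  te_library <- Biostrings::DNAStringSet(cons)
  S4Vectors::mcols(te_library)$te_class <- defs$te_class
  S4Vectors::mcols(te_library)$te_family <- defs$te_family
  # plant TE copies
  tc <- spec$te_copies
  copy_end <- integer(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    name <- tc$consensus[i]
    stopifnot(name %in% defs$name)
    copy <- .mutate_seq(cons[[name]], tc$divergence[i])
    if (tc$strand[i] == "-") {
      copy <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(copy)))
    }
    len <- nchar(copy)
    s <- tc$start[i]
    e <- s + len - 1L
    if (e > spec$chrom_lengths[[tc$chrom[i]]]) {
      stop("TE copy ", i, " extends beyond chromosome")
    }
    substr(chroms[[tc$chrom[i]]], s, e) <- copy
    copy_end[i] <- e
  }
  masked <- GenomicRanges::GRanges(
    seqnames = tc$chrom,
    ranges = IRanges::IRanges(start = tc$start, end = copy_end),
    strand = tc$strand,
    te_name = tc$consensus,
    te_class = defs$te_class[match(tc$consensus, defs$name)],
    te_family = defs$te_family[match(tc$consensus, defs$name)])
  # genes
  transcripts <- list()
  for (i in seq_len(nrow(spec$genes))) {
    g <- spec$genes[i, ]
    ex_start <- c(g$exon1_start, g$exon2_start)
    ex_end <- c(g$exon1_end, g$exon2_end)
    keep <- !is.na(ex_start)
    exons <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = ex_start[keep],
                                end = ex_end[keep]))
    utr3 <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$utr3_start, end = g$utr3_end))
    tid <- paste0(g$gene_id, "-RA")
    transcripts[[tid]] <- transcript_model(
      gene_id = g$gene_id, transcript_id = tid, chrom = g$chrom,
      strand = g$strand, exons = exons, utr3 = utr3)
  }
  # miRNA loci on chr1, clear of other planted features
  occupied <- suppressWarnings(
    c(GenomicRanges::granges(masked),
      do.call(c, unname(lapply(transcripts, function(t)
        GenomicRanges::granges(t$exons))))))
  mirna_loci <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(mirna_loci) < spec$mirna_loci && tries < 1000L) {
    tries <- tries + 1L
    chrom <- sample(names(spec$chrom_lengths), 1)
    s <- sample.int(spec$chrom_lengths[[chrom]] - 22L, 1)
    cand <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(s, width = 22L))
    suppressWarnings({
      free <- length(GenomicRanges::findOverlaps(cand, occupied)) == 0 &&
        (length(mirna_loci) == 0 ||
           length(GenomicRanges::findOverlaps(cand, mirna_loci)) == 0)
      if (free) mirna_loci <- c(mirna_loci, cand)
    })
  }
  # gene/TE overlap is disallowed
  gene_gr <- suppressWarnings(do.call(c, unname(
    lapply(transcripts, function(t) GenomicRanges::granges(t$exons)))))
  if (suppressWarnings(
    length(GenomicRanges::findOverlaps(gene_gr, masked))) > 0) {
    stop("planted gene overlaps a planted TE copy")
  }
  dom <- GenomicRanges::GRanges(
    seqnames = spec$chromatin_domains$chrom,
    ranges = IRanges::IRanges(start = spec$chromatin_domains$start,
                              end = spec$chromatin_domains$end))
  dom$class <- spec$chromatin_domains$class
  list(genome = Biostrings::DNAStringSet(
         stats::setNames(unlist(chroms), names(spec$chrom_lengths))),
       te_library = te_library, masked = masked,
       transcripts = transcripts, mirna_loci = mirna_loci,
       domains = dom, spec = spec)
}

# sample a 5'-end position in [lo, hi] on `strand` whose read-relative
# base at `rel_pos` equals `base` (want = TRUE) or not (want = FALSE);
# rejection sampling against the chromosome sequence
.sample_biased_pos <- function(chrom_seq, lo, hi, strand, rel_pos, base,
                               want, max_tries = 200L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (try in seq_len(max_tries)) {
    p <- sample(seq.int(lo, hi), 1L)
    gpos <- if (strand == "+") p + rel_pos - 1L else p - rel_pos + 1L
    b <- substr(chrom_seq, gpos, gpos)
    if (strand == "-") b <- comp[[b]]
    if ((b == base) == want) return(p)
  }
  p  # give up on the bias for this read
}

.read_from_genome <- function(chrom_seq, pos5, strand, len) {
  if (strand == "+") {
    s <- substr(chrom_seq, pos5, pos5 + len - 1L)
  } else {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(chrom_seq, pos5 - len + 1L, pos5))))
  }
  s
}

.draw_len <- function(n, length_probs) {
  as.integer(sample(names(length_probs), n, replace = TRUE,
                    prob = length_probs))
}

#' Simulate the small-RNA library from a built genome
#'
#' Emits reads in a documented order (cluster reads, TE primary /
#' secondary / sense reads per copy, genic reads, miRNA reads,
#' background), all extracted verbatim from the genome so every read
#' aligns exactly at its planted position. Cluster reads take the
#' planted dominant strand with probability `strand_bias` and a 5' U
#' with probability `u1_bias`. Each TE primary (antisense, 1U-biased)
#' spawns, with probability `pingpong_fraction`, a sense secondary whose
#' 5' end overlaps the primary's by exactly 10 nt — so the secondary's
#' position-10 base is the complement of the primary's position-1 base.
#' TE and genic reads concentrate on a small set of 5'-end hotspots and
#' carry multiplicities, as collapsed libraries do. Genic reads are
#' sampled within single exons (never across junctions) and fall in the
#' 3'-UTR with probability `utr3_weight`.
#'
#' @param spec the [sim_spec()] used for [build_genome()].
#' @param gb the genome bundle from [build_genome()].
#' @return list with `reads` (data.frame `id`, `seq`, `count`),
#'   `alignments` (`GRanges` with `read_id`, `n_genome_hits`; the planted
#'   placement of every read) and `truth` (data.frame with one row per
#'   read: `read_id`, `source`, `source_id`, `chrom`, `start`, `end`,
#'   `strand`, `orientation`, `partner_id`).
#' @export
simulate_reads <- function(spec, gb) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  genome_chr <- stats::setNames(as.character(gb$genome), names(gb$genome))
  reads <- list()
  truth <- list()
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    sprintf("r%06d", next_id)
  }
  emit <- function(seq, count, source, source_id, chrom, start, end,
                   strand, orientation = NA_character_,
                   partner_id = NA_character_) {
    id <- new_id()
    reads[[length(reads) + 1L]] <<- data.frame(
      id = id, seq = seq, count = as.integer(count),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = id, source = source, source_id = source_id,
      chrom = chrom, start = start, end = end, strand = strand,
      orientation = orientation, partner_id = partner_id,
      stringsAsFactors = FALSE)
    id
  }

  # --- cluster reads -------------------------------------------------
  pc <- spec$planted_clusters
  max_read_len <- max(as.integer(names(spec$length_probs)))
  if (any(pc$end - pc$start + 1L < max_read_len)) {
    stop("planted cluster interval shorter than the maximum read length")
  }
  for (ci in seq_len(nrow(pc))) {
    chrom <- pc$chrom[ci]
    cs <- genome_chr[[chrom]]
    dom_strand <- pc$dominant_strand[ci]
    lens <- .draw_len(pc$n_reads[ci], spec$length_probs)
    on_dom <- stats::runif(pc$n_reads[ci]) < pc$strand_bias[ci]
    want_u <- stats::runif(pc$n_reads[ci]) < spec$u1_bias
    for (ri in seq_len(pc$n_reads[ci])) {
      strand <- if (on_dom[ri]) dom_strand else
        setdiff(c("+", "-"), dom_strand)
      len <- lens[ri]
      lo <- if (strand == "+") pc$start[ci] else pc$start[ci] + len - 1L
      hi <- if (strand == "+") pc$end[ci] else pc$end[ci]
      pos5 <- .sample_biased_pos(cs, lo, hi, strand, 1L, "T", want_u[ri])
      seq <- .read_from_genome(cs, pos5, strand, len)
      gstart <- if (strand == "+") pos5 else pos5 - len + 1L
      emit(seq, 1L, "cluster", paste0("cluster", ci), chrom, gstart,
           gstart + len - 1L, strand)
    }
  }

  # --- TE reads ------------------------------------------------------
  tc <- spec$te_copies
  te_len <- .te_consensus_defs$length[
    match(tc$consensus, .te_consensus_defs$name)]
  for (ti in seq_len(nrow(tc))) {
    if (tc$n_primary[ti] + tc$n_sense[ti] == 0) next
    chrom <- tc$chrom[ti]
    cs <- genome_chr[[chrom]]
    copy_start <- tc$start[ti]
    copy_end <- copy_start + te_len[ti] - 1L
    copy_id <- paste0("te_copy", ti)
    # antisense = opposite of the copy's strand
    anti_strand <- if (tc$strand[ti] == "-") "+" else "-"
    sense_strand <- tc$strand[ti]
    max_len <- max(as.integer(names(spec$length_probs)))
    # primary (antisense) hotspots, split into 5'U and non-U groups
    margin <- max_len + 12L
    lo <- copy_start + margin
    hi <- copy_end - margin
    if (lo > hi) stop("TE copy ", ti, " too short for read sampling")
    n_hot <- spec$n_hotspots_primary
    hot_u <- vapply(seq_len(ceiling(n_hot / 2)), function(k)
      .sample_biased_pos(cs, lo, hi, anti_strand, 1L, "T", TRUE),
      numeric(1))
    hot_nu <- vapply(seq_len(n_hot - length(hot_u)), function(k)
      .sample_biased_pos(cs, lo, hi, anti_strand, 1L, "T", FALSE),
      numeric(1))
    # per-primary-hotspot multiplicities
    want_u <- stats::runif(tc$n_primary[ti]) < spec$u1_bias
    hot_of <- ifelse(want_u,
                     sample(seq_along(hot_u), tc$n_primary[ti],
                            replace = TRUE),
                     sample(seq_along(hot_nu), tc$n_primary[ti],
                            replace = TRUE))
    key <- paste(want_u, hot_of)
    has_partner <- stats::runif(tc$n_primary[ti]) < spec$pingpong_fraction
    for (k in unique(key)) {
      sel <- key == k
      pos5 <- if (want_u[which(sel)[1]])
        hot_u[hot_of[which(sel)[1]]] else hot_nu[hot_of[which(sel)[1]]]
      n_here <- sum(sel)
      n_paired <- sum(sel & has_partner)
      len <- .draw_len(1L, spec$length_probs)
      seq <- .read_from_genome(cs, pos5, anti_strand, len)
      gstart <- if (anti_strand == "+") pos5 else pos5 - len + 1L
      pid <- emit(seq, n_here, "te", copy_id, chrom, gstart,
                  gstart + len - 1L, anti_strand, "antisense")
      if (n_paired > 0) {
        # secondary on the opposite strand, 10-nt 5' overlap
        sec5 <- if (anti_strand == "+") pos5 + 9L else pos5 - 9L
        slen <- .draw_len(1L, spec$length_probs)
        sseq <- .read_from_genome(cs, sec5, sense_strand, slen)
        sstart <- if (sense_strand == "+") sec5 else sec5 - slen + 1L
        emit(sseq, n_paired, "te", copy_id, chrom, sstart,
             sstart + slen - 1L, sense_strand, "sense", pid)
      }
    }
    # independent sense reads with a position-10 A bias
    if (tc$n_sense[ti] > 0) {
      n_hot_s <- spec$n_hotspots_sense
      hot_a <- vapply(seq_len(ceiling(n_hot_s / 2)), function(k)
        .sample_biased_pos(cs, lo, hi, sense_strand, 10L, "A", TRUE),
        numeric(1))
      hot_na <- vapply(seq_len(n_hot_s - length(hot_a)), function(k)
        .sample_biased_pos(cs, lo, hi, sense_strand, 10L, "A", FALSE),
        numeric(1))
      want_a <- stats::runif(tc$n_sense[ti]) < spec$a10_bias
      hot_of <- ifelse(want_a,
                       sample(seq_along(hot_a), tc$n_sense[ti],
                              replace = TRUE),
                       sample(seq_along(hot_na), tc$n_sense[ti],
                              replace = TRUE))
      key <- paste(want_a, hot_of)
      for (k in unique(key)) {
        sel <- key == k
        pos5 <- if (want_a[which(sel)[1]])
          hot_a[hot_of[which(sel)[1]]] else hot_na[hot_of[which(sel)[1]]]
        len <- .draw_len(1L, spec$length_probs)
        seq <- .read_from_genome(cs, pos5, sense_strand, len)
        gstart <- if (sense_strand == "+") pos5 else pos5 - len + 1L
        emit(seq, sum(sel), "te", copy_id, chrom, gstart,
             gstart + len - 1L, sense_strand, "sense")
      }
    }
  }

  # --- genic reads ---------------------------------------------------
  for (gi in seq_len(nrow(spec$genes))) {
    g <- spec$genes[gi, ]
    chrom <- g$chrom
    cs <- genome_chr[[chrom]]
    max_len <- max(as.integer(names(spec$length_probs)))
    exons <- rbind(c(g$exon1_start, g$exon1_end),
                   if (!is.na(g$exon2_start))
                     c(g$exon2_start, g$exon2_end))
    # candidate genomic sub-intervals: inside the UTR, and exonic
    # outside the UTR; reads never cross an exon junction
    utr <- c(g$utr3_start, g$utr3_end)
    pick_pos <- function(in_utr, len, strand) {
      if (in_utr) {
        seg <- utr
      } else {
        # exon segments minus the UTR
        segs <- list()
        for (r in seq_len(nrow(exons))) {
          s <- exons[r, 1]; e <- exons[r, 2]
          if (utr[1] <= e && utr[2] >= s) {   # overlap
            if (s < utr[1]) segs[[length(segs) + 1]] <- c(s, utr[1] - 1L)
            if (e > utr[2]) segs[[length(segs) + 1]] <- c(utr[2] + 1L, e)
          } else segs[[length(segs) + 1]] <- c(s, e)
        }
        segs <- Filter(function(x) x[2] - x[1] + 1L >= len, segs)
        seg <- segs[[sample.int(length(segs), 1L)]]
      }
      gstart <- sample(seq.int(seg[1], seg[2] - len + 1L), 1L)
      c(gstart, gstart + len - 1L)
    }
    sense_strand <- g$strand
    anti_strand <- if (g$strand == "+") "-" else "+"
    # hotspots: (orientation, in_utr) combos with fixed positions
    mk_hot <- function(n, in_utr_flags) {
      lapply(seq_len(n), function(k) {
        len <- .draw_len(1L, spec$length_probs)
        list(interval = pick_pos(in_utr_flags[k], len, sense_strand),
             len = len, in_utr = in_utr_flags[k])
      })
    }
    ns <- spec$n_gene_hotspots_sense
    sense_hot <- mk_hot(ns, rep(c(TRUE, FALSE), length.out = ns))
    na <- spec$n_gene_hotspots_antisense
    anti_hot <- mk_hot(na, rep(c(TRUE, FALSE), length.out = na))
    alloc <- function(n_reads, hotspots, strand, orientation) {
      if (n_reads == 0) return(invisible(NULL))
      in_utr_flag <- vapply(hotspots, `[[`, logical(1), "in_utr")
      utr_pick <- stats::runif(n_reads) < g$utr3_weight
      idx_utr <- which(in_utr_flag)
      idx_non <- which(!in_utr_flag)
      hot_of <- ifelse(utr_pick,
                       idx_utr[sample.int(length(idx_utr), n_reads,
                                          replace = TRUE)],
                       idx_non[sample.int(length(idx_non), n_reads,
                                          replace = TRUE)])
      for (h in unique(hot_of)) {
        hs <- hotspots[[h]]
        n_here <- sum(hot_of == h)
        seq <- substr(cs, hs$interval[1], hs$interval[2])
        if (strand == "-") {
          seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        }
        emit(seq, n_here, "gene", g$gene_id, chrom, hs$interval[1],
             hs$interval[2], strand, orientation)
      }
    }
    alloc(g$n_sense, sense_hot, sense_strand, "sense")
    alloc(g$n_antisense, anti_hot, anti_strand, "antisense")
  }

  # --- miRNA reads ---------------------------------------------------
  if (spec$mirna_n > 0 && length(gb$mirna_loci) > 0) {
    split_n <- stats::rmultinom(
      1, spec$mirna_n,
      rep(1 / length(gb$mirna_loci), length(gb$mirna_loci)))[, 1]
    for (li in seq_along(gb$mirna_loci)) {
      if (split_n[li] == 0) next
      chrom <- as.character(
        GenomicRanges::seqnames(gb$mirna_loci[li]))
      s <- GenomicRanges::start(gb$mirna_loci[li])
      e <- GenomicRanges::end(gb$mirna_loci[li])
      seq <- substr(genome_chr[[chrom]], s, e)
      emit(seq, split_n[li], "mirna", paste0("mir", li), chrom, s, e,
           "+", "sense")
    }
  }

  # --- background reads ----------------------------------------------
  n_windows <- sum(spec$chrom_lengths %/% spec$window_size)
  n_bg <- stats::rpois(1, spec$background_per_window * n_windows)
  for (bi in seq_len(n_bg)) {
    chrom <- sample(names(spec$chrom_lengths), 1,
                    prob = spec$chrom_lengths / sum(spec$chrom_lengths))
    len <- .draw_len(1L, spec$length_probs)
    gstart <- sample.int(spec$chrom_lengths[[chrom]] - len, 1L)
    strand <- sample(c("+", "-"), 1)
    seq <- substr(genome_chr[[chrom]], gstart, gstart + len - 1L)
    if (strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    }
    emit(seq, 1L, "background", "bg", chrom, gstart, gstart + len - 1L,
         strand)
  }

  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  n_hits <- count_genome_occurrences(reads$seq, gb$genome)
  al <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = truth$start, end = truth$end),
    strand = truth$strand)
  al$read_id <- truth$read_id
  al$n_genome_hits <- n_hits
  list(reads = reads, alignments = al, truth = truth)
}

#' Write all simulator outputs to a directory
#'
#' Reads as FASTQ, alignments as BED6, TE copies and clusters as truth
#' BEDs, the truth table as TSV and the genome and TE library as FASTA.
#'
#' @param sim output of [simulate_reads()].
#' @param gb genome bundle from [build_genome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, gb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reads_fastq(sim$reads, file.path(dir, "reads.fastq"))
  write_alignments_bed(sim$alignments, file.path(dir, "alignments.bed"))
  Biostrings::writeXStringSet(gb$genome, file.path(dir, "genome.fa"))
  lib <- gb$te_library
  info <- S4Vectors::mcols(lib)
  out_lib <- Biostrings::DNAStringSet(as.character(lib))
  names(out_lib) <- paste0(names(lib), "#", info$te_class, "/",
                           info$te_family)
  Biostrings::writeXStringSet(out_lib, file.path(dir, "te_library.fa"))
  rtracklayer::export(gb$masked, file.path(dir, "te_copies.bed"),
                      format = "bed")
  dom <- GenomicRanges::granges(gb$domains)
  dom$name <- gb$domains$class
  rtracklayer::export(dom, file.path(dir, "domains.bed"), format = "bed")
  pc <- gb$spec$planted_clusters
  cl <- GenomicRanges::GRanges(
    pc$chrom, IRanges::IRanges(pc$start, pc$end))
  cl$name <- paste0("cluster", seq_len(nrow(pc)))
  rtracklayer::export(cl, file.path(dir, "planted_clusters.bed"),
                      format = "bed")
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
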
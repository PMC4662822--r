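#' Fraction of reads with a given base at a given position
#'
#' The 1U bias (Uridine at position 1) and 10A bias (Adenine at position
#' 10) are the positional hallmarks of primary and secondary piRNAs.
#' Positions are 1-based from the read's 5' end; reads shorter than the
#' queried position are excluded from the denominator. U and T are
#' equivalent.
#'
#' @param reads reads data.frame.
#' @param position 1-based position.
#' @param base single base (`A`, `C`, `G`, `T` or `U`).
#' @param weighted weight reads by their multiplicity (default TRUE).
#' @return numeric fraction; error when no read is long enough.
#' @export
base_fraction_at <- function(reads, position, base, weighted = TRUE) {
  stopifnot(position >= 1)
  base <- chartr("U", "T", toupper(base))
  long_enough <- nchar(reads$seq) >= position
  if (!any(long_enough)) stop("no read covers position ", position)
  sub <- reads[long_enough, , drop = FALSE]
  w <- if (weighted) sub$count else rep(1, nrow(sub))
  hit <- substr(sub$seq, position, position) == base
  sum(w[hit]) / sum(w)
}

#' 1U/10A signature table for sense and antisense TE reads
#'
#' Computes the four positional-bias fractions (1U and 10A for the sense
#' and antisense TE-hit subsets). Cells whose subset is empty are `NA`.
#'
#' @param hits TE hit table ([consensus_map()] / [overlap_map()]).
#' @param reads reads data.frame covering the hit reads.
#' @param weighted weight by multiplicity (default TRUE).
#' @return data.frame with columns `orientation`, `u1`, `a10`.
#' @export
te_signature_table <- function(hits, reads, weighted = TRUE) {
  cell <- function(orientation, position, base) {
    ids <- hits$read_id[hits$orientation == orientation]
    sub <- reads[reads$id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    tryCatch(base_fraction_at(sub, position, base, weighted),
             error = function(e) NA_real_)
  }
  data.frame(
    orientation = c("sense", "antisense"),
    u1 = c(cell("sense", 1, "U"), cell("antisense", 1, "U")),
    a10 = c(cell("sense", 10, "A"), cell("antisense", 10, "A")))
}

.five_prime_tables <- function(alignments, read_counts, weighting) {
  chrom <- as.character(GenomicRanges::seqnames(alignments))
  minus <- as.character(GenomicRanges::strand(alignments)) == "-"
  pos <- five_prime_pos(alignments)
  w <- rep(1, length(alignments))
  if (!is.null(read_counts)) {
    w <- read_counts[alignments$read_id]
    w[is.na(w)] <- 1
  }
  data.frame(chrom = chrom, minus = minus, pos = pos, w = w,
             read_id = alignments$read_id, stringsAsFactors = FALSE)
}

#' Ping-pong 5'-overlap histogram
#'
#' For a plus-strand 5' end at position p and a minus-strand 5' end at
#' position q on the same reference, the pair overlaps by k = q - p + 1
#' nt. The ping-pong amplification cycle, whose PIWI-mediated cleavage
#' falls between positions 10 and 11 of the complementary RNA, leaves a
#' peak at exactly k = 10. The histogram collects all opposite-strand
#' 5'-end pairs at offsets 1..`k_max`; `z10` is the z-score of the k = 10
#' weight against the remaining offsets.
#'
#' Two weightings: `"reads"` (default) counts, for each k, the number of
#' distinct reads having at least one opposite-strand partner at that
#' offset; `"pairs"` sums the product of read multiplicities over all
#' 5'-end pairs.
#'
#' @param alignments alignment `GRanges` on one reference coordinate
#'   system.
#' @param read_counts optional named vector of read multiplicities (names
#'   are read ids) for pair weighting.
#' @param k_max largest overlap offset considered (default 30).
#' @param weighting `"reads"` or `"pairs"`.
#' @return an object of class `pingpong_profile`: list with
#'   `overlap_counts` (named numeric, offsets 1..k_max), `z10`, `n_pairs`
#'   (number of distinct 5'-position pairs), `weighting`.
#' @export
ping_pong_histogram <- function(alignments, read_counts = NULL,
                                k_max = 30L,
                                weighting = c("reads", "pairs")) {
  weighting <- match.arg(weighting)
  counts <- stats::setNames(numeric(k_max), seq_len(k_max))
  n_pairs <- 0L
  tab <- .five_prime_tables(alignments, read_counts, weighting)
  for (chrom in unique(tab$chrom)) {
    t <- tab[tab$chrom == chrom, , drop = FALSE]
    pl <- t[!t$minus, , drop = FALSE]
    mi <- t[t$minus, , drop = FALSE]
    if (nrow(pl) == 0 || nrow(mi) == 0) next
    # aggregate weights and read sets by 5' position
    wp <- tapply(pl$w, pl$pos, sum)
    wm <- tapply(mi$w, mi$pos, sum)
    ppos <- as.integer(names(wp))
    mpos <- as.integer(names(wm))
    for (k in seq_len(k_max)) {
      qs <- ppos + k - 1L
      hit <- qs %in% mpos
      if (!any(hit)) next
      n_pairs <- n_pairs + sum(hit)
      if (weighting == "pairs") {
        counts[k] <- counts[k] +
          sum(wp[hit] * wm[as.character(qs[hit])])
      } else {
        p_in <- ppos[hit]
        m_in <- qs[hit]
        counts[k] <- counts[k] +
          length(unique(pl$read_id[pl$pos %in% p_in])) +
          length(unique(mi$read_id[mi$pos %in% m_in]))
      }
    }
  }
  bg <- counts[-10]
  z10 <- if (stats::sd(bg) > 0)
    (counts[[10]] - mean(bg)) / stats::sd(bg) else NA_real_
  if (sum(counts) == 0) z10 <- NA_real_
  structure(list(overlap_counts = counts, z10 = z10, n_pairs = n_pairs,
                 weighting = weighting),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  peak <- as.integer(names(which.max(x$overlap_counts)))
  cat("<pingpong_profile> peak offset ", peak, " nt; z10 = ",
      round(x$z10, 2), "; ", x$n_pairs, " 5'-position pairs (",
      x$weighting, "-weighted)\n", sep = "")
  invisible(x)
}

#' Extract the ping-pong read pairs at a fixed overlap offset
#'
#' @param alignments alignment `GRanges`.
#' @param k overlap offset (default 10, the ping-pong signature).
#' @return data.frame of `plus_read` / `minus_read` id pairs whose 5'
#'   ends overlap by exactly k nt.
#' @export
ping_pong_pairs <- function(alignments, k = 10L) {
  tab <- .five_prime_tables(alignments, NULL, "reads")
  out <- list()
  for (chrom in unique(tab$chrom)) {
    t <- tab[tab$chrom == chrom, , drop = FALSE]
    pl <- t[!t$minus, , drop = FALSE]
    mi <- t[t$minus, , drop = FALSE]
    if (nrow(pl) == 0 || nrow(mi) == 0) next
    m <- merge(data.frame(plus_read = pl$read_id, q = pl$pos + k - 1L),
               data.frame(minus_read = mi$read_id, q = mi$pos))
    if (nrow(m) > 0) {
      out[[length(out) + 1L]] <- m[, c("plus_read", "minus_read")]
    }
  }
  if (length(out) == 0) {
    return(data.frame(plus_read = character(),
                      minus_read = character()))
  }
  do.call(rbind, out)
}

#' Nucleotide composition of the 10-nt ping-pong overlap
#'
#' Per-position base frequencies (positions 1..10 numbered from each
#' partner read's own 5' end) over all partner reads of pairs with a
#' 10-nt 5' overlap. For a perfect pair, position 10 of one partner is
#' the complement of position 1 of the other.
#'
#' @param pairs pair table from [ping_pong_pairs()] at k = 10.
#' @param reads reads data.frame supplying sequences.
#' @return a 10 x 4 matrix of frequencies (columns `A`, `C`, `G`, `U`);
#'   each covered row sums to 1. Empty matrix when there are no pairs.
#' @export
overlap_composition <- function(pairs, reads) {
  bases <- c("A", "C", "G", "U")
  if (nrow(pairs) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 4,
                  dimnames = list(NULL, bases)))
  }
  ids <- c(pairs$plus_read, pairs$minus_read)
  seqs <- reads$seq[match(ids, reads$id)]
  if (anyNA(seqs)) stop("pair read missing from reads table")
  mat <- matrix(0, nrow = 10, ncol = 4,
                dimnames = list(1:10, bases))
  for (p in 1:10) {
    b <- substr(seqs, p, p)
    b <- chartr("T", "U", b)
    covered <- nchar(seqs) >= p
    t <- table(factor(b[covered], levels = bases))
    if (sum(t) > 0) mat[p, ] <- as.numeric(t) / sum(t)
  }
  mat
}
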
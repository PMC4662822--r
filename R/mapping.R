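#' Exact-match read mapping against a small genome
#'
#' Places every read at all of its exact full-length occurrences in the
#' genome (both strands) and reports the total number of genomic hits per
#' read. Intended for the small synthetic genomes this package simulates;
#' for real assemblies, precomputed BED alignments are the supported input.
#'
#' Distinct sequences are grouped by length and searched with a
#' [Biostrings::PDict], so runtime scales with genome size, not read count.
#'
#' @param reads reads data.frame (`id`, `seq`, `count`).
#' @param genome a named [Biostrings::DNAStringSet].
#' @return a `GRanges` with one row per placement, metadata columns
#'   `read_id` and `n_genome_hits` (total placements of that read).
#' @export
map_reads_exact <- function(reads, genome) {
  if (nrow(reads) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$read_id <- character()
    gr$n_genome_hits <- integer()
    return(gr)
  }
  seqs <- reads$seq
  uniq <- !duplicated(seqs)
  useq <- seqs[uniq]
  res <- vector("list", 0L)
  for (len in sort(unique(nchar(useq)))) {
    sub <- useq[nchar(useq) == len]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    for (chrom in names(genome)) {
      subject <- genome[[chrom]]
      clen <- length(subject)
      for (str in c("+", "-")) {
        target <- if (str == "+") subject else
          Biostrings::reverseComplement(subject)
        m <- Biostrings::matchPDict(pd, target)
        starts <- IRanges::start(m)
        n_per <- lengths(starts)
        if (sum(n_per) == 0) next
        seq_idx <- rep(seq_along(sub), n_per)
        st <- unlist(starts, use.names = FALSE)
        if (str == "-") st <- clen - (st + len - 1L) + 1L
        res[[length(res) + 1L]] <- data.frame(
          seq = sub[seq_idx], chrom = chrom, start = st,
          strand = str, len = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$read_id <- character()
    gr$n_genome_hits <- integer()
    return(gr)
  }
  hits <- do.call(rbind, res)
  tab <- table(hits$seq)
  hits$n <- as.integer(tab[hits$seq])
  # expand placements to every read carrying that sequence
  all <- merge(data.frame(read_id = reads$id, seq = seqs,
                          stringsAsFactors = FALSE),
               hits, by = "seq")
  gr <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(start = all$start, width = all$len),
    strand = all$strand)
  gr$read_id <- all$read_id
  gr$n_genome_hits <- all$n
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# Concatenate a DNAStringSet into one subject with N spacers (exact and
# <=3-mismatch matches cannot bridge segments); returns segment bounds.
.concat_library <- function(lib, spacer = 35L) {
  lens <- Biostrings::width(lib)
  subject <- Biostrings::DNAString(
    paste(as.character(lib), collapse = strrep("N", spacer)))
  starts <- cumsum(c(1L, utils::head(lens + spacer, -1L)))
  list(subject = subject, starts = starts, ends = starts + lens - 1L)
}

# Exact full-length match starts of many sequences against one subject,
# grouped by length through a PDict; sequences with ambiguity codes fall
# back to matchPattern. Returns a list of integer vectors.
.exact_starts <- function(seqs, subject) {
  out <- rep(list(integer()), length(seqs))
  if (length(seqs) == 0) return(out)
  clean <- !grepl("[^ACGT]", seqs)
  for (len in unique(nchar(seqs[clean]))) {
    idx <- which(clean & nchar(seqs) == len)
    if (len > length(subject)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    m <- Biostrings::matchPDict(pd, subject)
    out[idx] <- as.list(IRanges::start(m))
  }
  for (i in which(!clean)) {
    if (nchar(seqs[i]) > length(subject)) next
    out[[i]] <- IRanges::start(Biostrings::matchPattern(
      Biostrings::DNAString(seqs[i]), subject))
  }
  out
}

#' Number of exact genomic occurrences of each sequence
#'
#' @param seqs character vector of DNA sequences.
#' @param genome named `DNAStringSet`.
#' @return integer vector (same length as `seqs`) of total occurrences on
#'   both strands.
#' @export
count_genome_occurrences <- function(seqs, genome) {
  if (length(seqs) == 0) return(integer())
  useq <- unique(seqs)
  counts <- stats::setNames(integer(length(useq)), useq)
  for (len in sort(unique(nchar(useq)))) {
    sub <- useq[nchar(useq) == len]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    for (chrom in names(genome)) {
      subject <- genome[[chrom]]
      counts[sub] <- counts[sub] +
        Biostrings::countPDict(pd, subject) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(subject))
    }
  }
  unname(counts[seqs])
}
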
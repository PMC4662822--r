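#' Read a small-RNA library from FASTA or FASTQ
#'
#' Reads a (possibly collapsed) small-RNA library. `U` bases are normalised
#' to `T` at parse time so all downstream sequence comparisons are in DNA
#' space. With `count_dialect = "suffix"` a trailing `_xN` or `-N` on the
#' record identifier is parsed as the read's multiplicity in the sequenced
#' library (the common collapsed-FASTA convention); with `"none"` every
#' record has count 1. Gzip-compressed files are accepted.
#'
#' @param path path to a FASTA or FASTQ file (optionally `.gz`).
#' @param count_dialect `"suffix"` (default) or `"none"`.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` to guess from the file
#'   extension.
#' @return a data.frame with columns `id` (identifier, suffix stripped when
#'   parsed as a count), `seq` (ACGTN string) and `count` (integer >= 1).
#' @export
read_small_rna_fasta <- function(path, count_dialect = c("suffix", "none"),
                                 format = c("auto", "fasta", "fastq")) {
  count_dialect <- match.arg(count_dialect)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1]],
         "': sequence has characters outside {A,C,G,T,U,N}")
  }
  counts <- rep.int(1L, length(ss))
  if (count_dialect == "suffix") {
    m <- regmatches(ids, regexec("^(.*?)(?:_x([0-9]+)|-([0-9]+))$", ids))
    has_suffix <- lengths(m) == 4L & grepl("(_x[0-9]+|-[0-9]+)$", ids)
    for (i in which(has_suffix)) {
      parts <- m[[i]]
      n <- suppressWarnings(as.integer(parts[parts != ""][3]))
      if (!is.na(n) && n >= 1L) {
        counts[i] <- n
        ids[i] <- parts[2]
      }
    }
  }
  data.frame(id = ids, seq = unname(seqs), count = counts,
             stringsAsFactors = FALSE)
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard whitespace-separated RepeatMasker `.out` layout
#' (two header lines plus a blank line before the data). The 1-based
#' inclusive genomic coordinates map directly onto `GRanges`; the
#' `class/family` column is split at its first `/` into a TE class and
#' family (family is `NA` when absent). A `C` in the orientation column
#' becomes strand `-`.
#'
#' @param path path to a RepeatMasker `.out` file (optionally gzipped).
#' @return a [GenomicRanges::GRanges] of masked intervals with metadata
#'   columns `te_name`, `te_class` and `te_family`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_data <- grepl("^\\s*[0-9]+\\s", lines)
  if (!any(is_data)) {
    return(GenomicRanges::GRanges(
      te_name = character(), te_class = character(),
      te_family = character()))
  }
  rows <- lines[is_data]
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    bad <- which(is_data)[which(nf < 14L)[1]]
    stop("RepeatMasker .out line ", bad, ": expected >= 14 columns, got ",
         min(nf))
  }
  take <- function(k) vapply(fields, `[[`, character(1), k)
  chrom <- take(5)
  begin <- as.integer(take(6))
  end <- as.integer(take(7))
  orient <- take(9)
  te_name <- take(10)
  cf <- take(11)
  slash <- regexpr("/", cf, fixed = TRUE)
  te_class <- ifelse(slash > 0, substr(cf, 1, slash - 1), cf)
  te_family <- ifelse(slash > 0, substr(cf, slash + 1, nchar(cf)),
                      NA_character_)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = begin, end = end),
    strand = ifelse(orient == "C", "-", "+"),
    te_name = te_name, te_class = te_class, te_family = te_family)
}

#' A single transcript model
#'
#' Lightweight container for one transcript: its identifiers, strand,
#' exons (a sorted, non-overlapping `GRanges`) and, when annotated, a
#' single 3'-UTR interval contained in the exon union.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons a `GRanges` of exon intervals (any order; stored sorted by
#'   genomic coordinate).
#' @param utr3 optional `GRanges` of length 1, or `NULL` when the
#'   transcript has no annotated 3'-UTR.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exons, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- GenomicRanges::sort(exons)
  if (length(exons) > 1 &&
      any(IRanges::width(IRanges::pintersect(
        IRanges::ranges(exons[-length(exons)]),
        IRanges::ranges(exons[-1]), resolve.empty = "start.x")) > 0)) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (!is.null(utr3)) {
    cov <- sum(IRanges::width(IRanges::intersect(
      IRanges::ranges(utr3), IRanges::ranges(exons))))
    if (cov != sum(IRanges::width(utr3)))
      stop("transcript ", transcript_id, ": 3'-UTR not within exon union")
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 utr3 = utr3),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_id, ") ",
      x$chrom, x$strand, " ", length(x$exons), " exon(s), 3'UTR: ",
      if (is.null(x$utr3)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Read transcript models from a GFF3 file
#'
#' Expects gene/mRNA/exon/three_prime_UTR features linked by `Parent`
#' attributes. Exons or UTRs whose parent transcript cannot be resolved are
#' skipped with a warning; overlapping exons within one transcript are an
#' error. When a transcript carries several `three_prime_UTR` segments the
#' stored 3'-UTR is their enclosing range. Transcripts without a
#' `three_prime_UTR` feature get `utr3 = NULL`.
#'
#' @param path path to a GFF3 file.
#' @return a named list of [transcript_model] objects (names are
#'   transcript ids).
#' @export
read_gff3_transcripts <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gff$type)
  first_chr <- function(x) if (length(x)) as.character(x)[1] else NA_character_
  mrna <- gff[typ %in% c("mRNA", "transcript")]
  tx_ids <- as.character(mrna$ID)
  tx_parent <- vapply(mrna$Parent, first_chr, character(1))
  out <- list()
  for (i in seq_along(mrna)) {
    tid <- tx_ids[i]
    kids <- gff[typ %in% c("exon", "three_prime_UTR")]
    kp <- vapply(kids$Parent, first_chr, character(1))
    mine <- kids[!is.na(kp) & kp == tid]
    exons <- mine[as.character(mine$type) == "exon"]
    utr <- mine[as.character(mine$type) == "three_prime_UTR"]
    if (length(exons) == 0) next
    utr3 <- if (length(utr) > 0) range(GenomicRanges::granges(utr)) else NULL
    out[[tid]] <- transcript_model(
      gene_id = if (!is.na(tx_parent[i])) tx_parent[i] else tid,
      transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(mrna[i]))[1],
      strand = as.character(GenomicRanges::strand(mrna[i]))[1],
      exons = GenomicRanges::granges(exons),
      utr3 = utr3)
  }
  # orphan children: exon/UTR features whose Parent is not a known transcript
  kids <- gff[typ %in% c("exon", "three_prime_UTR")]
  kp <- vapply(kids$Parent, first_chr, character(1))
  orphans <- !is.na(kp) & !(kp %in% tx_ids)
  if (any(orphans)) {
    warning(sum(orphans), " exon/UTR feature(s) with unresolvable Parent ",
            "skipped")
  }
  out
}

#' Read genomic read alignments from a BED6 file
#'
#' BED6 with `name` = read id and `score` = number of genomic placements of
#' that read (genome-hit multiplicity). rtracklayer performs the 0-based
#' half-open to 1-based closed conversion.
#'
#' @param path path to a BED6 file.
#' @return a `GRanges` with metadata columns `read_id` and `n_genome_hits`.
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(gr)
  out$read_id <- as.character(gr$name)
  out$n_genome_hits <- as.integer(gr$score)
  out$n_genome_hits[is.na(out$n_genome_hits)] <- 1L
  out
}

#' Write read alignments to BED6
#'
#' @param alignments a `GRanges` with `read_id` and `n_genome_hits`.
#' @param path output path.
#' @export
write_alignments_bed <- function(alignments, path) {
  gr <- GenomicRanges::granges(alignments)
  gr$name <- alignments$read_id
  gr$score <- alignments$n_genome_hits
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write called piRNA clusters to BED6
#'
#' One line per cluster: `name` = `cluster_<rank>`, `score` = number of
#' unique piRNAs, `strand` = the dominant strand for strand-biased clusters
#' (strong or near-exclusive bias) and `.` for unbiased (bidirectional)
#' clusters. The file round-trips losslessly through [read_clusters_bed()]
#' for these fields.
#'
#' @param clusters a cluster `GRanges` as returned by [call_clusters()]
#'   after [classify_strand_bias()] and [rank_clusters()].
#' @param path output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (length(clusters) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::granges(clusters)
  rank <- if (!is.null(clusters$rank)) clusters$rank else seq_along(clusters)
  gr$name <- paste0("cluster_", rank)
  gr$score <- clusters$n_unique_pirnas
  str <- rep("*", length(clusters))  # exported as '.' in BED
  if (!is.null(clusters$bias_class)) {
    biased <- clusters$bias_class %in% c("strong", "near_exclusive") &
      clusters$dominant_strand %in% c("+", "-")
    str[biased] <- clusters$dominant_strand[biased]
  }
  GenomicRanges::strand(gr) <- str
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a cluster BED6 file written by [write_clusters_bed()]
#'
#' @param path path to the BED file.
#' @return a `GRanges` with `rank`, `n_unique_pirnas` and strand.
#' @export
read_clusters_bed <- function(path) {
  if (file.size(path) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$rank <- integer()
    gr$n_unique_pirnas <- integer()
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr))
  out$rank <- as.integer(sub("^cluster_", "", gr$name))
  out$n_unique_pirnas <- as.integer(gr$score)
  out
}

#' Read chromatin-domain classes from a BED file
#'
#' BED intervals whose `name` column is one of `pericentromeric`,
#' `intercalary_diffuse`, `intercalary_compact`, `euchromatic`.
#'
#' @param path path to the domain BED file.
#' @return a `GRanges` with metadata column `class`.
#' @export
read_domains_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- as.character(gr$name)
  known <- c("pericentromeric", "intercalary_diffuse",
             "intercalary_compact", "euchromatic")
  if (!all(cls %in% known)) {
    stop("unknown chromatin class(es): ",
         paste(setdiff(cls, known), collapse = ", "))
  }
  out <- GenomicRanges::granges(gr)
  out$class <- cls
  out
}

#' Read a TE consensus library from FASTA
#'
#' Headers follow the RepeatMasker convention `name#class/family` (family
#' optional). U bases are normalised to T.
#'
#' @param path path to the consensus FASTA.
#' @return a [Biostrings::DNAStringSet] named by TE name, with metadata
#'   columns `te_class` and `te_family`.
#' @export
read_te_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  name <- sub("#.*$", "", hdr)
  if (anyDuplicated(name)) stop("duplicate TE consensus name in ", path)
  rest <- ifelse(grepl("#", hdr), sub("^[^#]*#", "", hdr), NA_character_)
  te_class <- ifelse(is.na(rest), "Unknown", sub("/.*$", "", rest))
  te_family <- ifelse(!is.na(rest) & grepl("/", rest),
                      sub("^[^/]*/", "", rest), NA_character_)
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- name
  S4Vectors::mcols(out)$te_class <- te_class
  S4Vectors::mcols(out)$te_family <- te_family
  out
}

#' Write a small-RNA library to FASTQ
#'
#' Constant maximal quality is written (the simulator does not model
#' sequencing error). Collapsed counts are encoded as an `_xN` id suffix.
#'
#' @param reads a reads data.frame (`id`, `seq`, `count`).
#' @param path output path (`.gz` accepted).
#' @param count_suffix append `_xN` to ids when count > 1 (default TRUE).
#' @export
write_reads_fastq <- function(reads, path, count_suffix = TRUE) {
  ids <- reads$id
  if (count_suffix) {
    many <- reads$count > 1L
    ids[many] <- paste0(ids[many], "_x", reads$count[many])
  }
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(
    ss, path, format = "fastq", qualities = qual,
    compress = grepl("\\.gz$", path))
  invisible(path)
}
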
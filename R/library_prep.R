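#' Retain reads within a length window
#'
#' The piRNA-sized fraction of an ovarian small-RNA library is taken as
#' 24-29 nt (the broad secondary peak of the length distribution, apex at
#' 27 nt, distinct from the 22-nt miRNA peak).
#'
#' @param reads a reads data.frame (`id`, `seq`, `count`).
#' @param min_len,max_len inclusive length bounds (defaults 24 and 29).
#' @return the retained rows, counts preserved.
#' @export
size_filter <- function(reads, min_len = 24L, max_len = 29L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Collapse a library to distinct sequences
#'
#' Reads present more than once are reduced to a single occurrence with
#' count 1; the original summed multiplicity is kept alongside in
#' `orig_count`. Output is ordered lexicographically by sequence so the
#' operation is deterministic.
#'
#' @param reads a reads data.frame.
#' @return data.frame with columns `id` (the first contributing id in
#'   input order), `seq`, `count` (all 1) and `orig_count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) {
    return(data.frame(id = character(), seq = character(),
                      count = integer(), orig_count = integer()))
  }
  split_idx <- split(seq_len(nrow(reads)), reads$seq)  # names sorted
  idx1 <- vapply(split_idx, `[[`, integer(1), 1L)
  orig <- vapply(split_idx, function(i) sum(reads$count[i]), numeric(1))
  data.frame(id = reads$id[idx1], seq = names(split_idx),
             count = rep.int(1L, length(split_idx)),
             orig_count = as.integer(orig),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify reads as genome-unique or multi-mappers
#'
#' @param alignments alignment `GRanges` with a `read_id` column; one row
#'   per genomic placement. When an `n_genome_hits` metadata column is
#'   present (placements represented by a single row, as in BED exports
#'   that record multiplicity in the score), the declared value is
#'   honoured; the placement count per read is the larger of the row
#'   tally and the declared multiplicity.
#' @param read_ids optional character vector of all read ids to classify;
#'   ids with no alignment are tallied as unmapped.
#' @return list with `n_hits` (named integer vector of placements per
#'   read), `unique_ids` (exactly one placement), `multi_ids` and
#'   `unmapped_ids`.
#' @export
classify_uniqueness <- function(alignments, read_ids = NULL) {
  tab <- table(alignments$read_id)
  n_hits <- as.integer(tab)
  names(n_hits) <- names(tab)
  if (!is.null(alignments$n_genome_hits)) {
    declared <- tapply(alignments$n_genome_hits, alignments$read_id, max)
    n_hits <- pmax(n_hits, as.integer(declared[names(n_hits)]))
  }
  unmapped <- character()
  if (!is.null(read_ids)) {
    unmapped <- setdiff(read_ids, names(n_hits))
  }
  list(n_hits = n_hits,
       unique_ids = names(n_hits)[n_hits == 1L],
       multi_ids = names(n_hits)[n_hits > 1L],
       unmapped_ids = unmapped)
}

#' Build the three library strata
#'
#' NCNU: all reads with any genomic placement, duplicates and multi-mappers
#' kept. NCU: genome-unique mappers, duplicates kept. CU: collapsed
#' genome-unique (distinct sequences, one placement each).
#'
#' @param reads reads data.frame.
#' @param alignments alignment `GRanges` (`read_id`, `n_genome_hits`); one
#'   row per placement per read.
#' @return named list of three strata; each stratum is a list with `label`,
#'   `reads`, `alignments`, `total_reads` (sum of counts) and
#'   `total_genome_mappers`.
#' @export
build_strata <- function(reads, alignments) {
  uniq <- classify_uniqueness(alignments, reads$id)
  mapped <- reads[reads$id %in% names(uniq$n_hits), , drop = FALSE]
  stratum <- function(label, rd, al) {
    list(label = label, reads = rd, alignments = al,
         total_reads = sum(rd$count),
         total_genome_mappers = sum(rd$count))
  }
  ncnu <- stratum("NCNU", mapped, alignments)
  ncu_reads <- mapped[mapped$id %in% uniq$unique_ids, , drop = FALSE]
  ncu_al <- alignments[alignments$read_id %in% uniq$unique_ids]
  ncu <- stratum("NCU", ncu_reads, ncu_al)
  cu_reads <- collapse_reads(ncu_reads)
  # after collapsing, keep one alignment per distinct sequence
  keep_ids <- cu_reads$id
  cu_al <- ncu_al[match(keep_ids, ncu_al$read_id)]
  cu <- stratum("CU", cu_reads, cu_al)
  list(NCNU = ncnu, NCU = ncu, CU = cu)
}

.exact_substring_match <- function(seqs, refs) {
  # TRUE for each seq that occurs verbatim (either strand) in any ref
  cat <- .concat_library(refs)
  cat_rc <- .concat_library(Biostrings::reverseComplement(refs))
  lengths(.exact_starts(seqs, cat$subject)) > 0 |
    lengths(.exact_starts(seqs, cat_rc$subject)) > 0
}

#' Annotate reads into small-RNA categories
#'
#' One category per read under the precedence
#' miRNA > rRNA > tRNA > snRNA > TE > gene > unannotated. Structural-RNA
#' categories require an exact (0-mismatch) match of the read within a
#' reference sequence; TE matches allow up to `max_mismatches` against the
#' consensus library (via [consensus_map()]); gene matches are exact
#' full-length matches to a spliced transcript sequence. The precedence
#' order is configurable.
#'
#' @param reads reads data.frame.
#' @param structural_refs named list of `DNAStringSet`s; recognised names
#'   are `mirna`, `rrna`, `trna`, `snrna` (any may be missing).
#' @param te_library TE consensus `DNAStringSet` (see [read_te_fasta()]),
#'   or `NULL` to skip the TE category.
#' @param transcripts list of [transcript_model]s, or `NULL`.
#' @param genome `DNAStringSet` genome (needed when `transcripts` given).
#' @param max_mismatches mismatches allowed for the TE category (default 3).
#' @param precedence category order, highest priority first.
#' @return factor of categories, named by read id, levels
#'   `miRNA, rRNA, tRNA, snRNA, TE, gene, unannotated`.
#' @export
annotate_reads <- function(reads, structural_refs = list(),
                           te_library = NULL, transcripts = NULL,
                           genome = NULL, max_mismatches = 3L,
                           precedence = c("miRNA", "rRNA", "tRNA", "snRNA",
                                          "TE", "gene", "unannotated")) {
  levels_all <- c("miRNA", "rRNA", "tRNA", "snRNA", "TE", "gene",
                  "unannotated")
  stopifnot(all(precedence %in% levels_all))
  hits <- list()
  key <- c(miRNA = "mirna", rRNA = "rrna", tRNA = "trna", snRNA = "snrna")
  for (cat in names(key)) {
    refs <- structural_refs[[key[[cat]]]]
    hits[[cat]] <- if (is.null(refs)) logical(nrow(reads)) else
      .exact_substring_match(reads$seq, refs)
  }
  hits[["TE"]] <- if (is.null(te_library)) logical(nrow(reads)) else
    reads$id %in% consensus_map(reads, te_library,
                                max_mismatches = max_mismatches)$read_id
  hits[["gene"]] <- if (is.null(transcripts) || length(transcripts) == 0)
    logical(nrow(reads)) else
    reads$id %in% map_to_transcripts(reads, transcripts, genome)$read_id
  out <- rep("unannotated", nrow(reads))
  for (cat in rev(setdiff(precedence, "unannotated"))) {
    out[hits[[cat]]] <- cat
  }
  factor(stats::setNames(out, reads$id), levels = levels_all)
}

#' Drop structural small RNAs, keeping bona fide piRNA candidates
#'
#' Bona fide reads exclude the miRNA, rRNA, tRNA and snRNA categories.
#'
#' @param reads reads data.frame.
#' @param categories factor from [annotate_reads()] (aligned with `reads`
#'   rows or named by read id).
#' @return the retained rows of `reads`.
#' @export
bona_fide_filter <- function(reads, categories) {
  if (!is.null(names(categories))) {
    categories <- categories[reads$id]
  }
  keep <- !(as.character(categories) %in% c("miRNA", "rRNA", "tRNA",
                                            "snRNA"))
  reads[keep, , drop = FALSE]
}

#' Category summary table
#'
#' Tab-separated-ready summary (category, reads, fraction) of an
#' annotation run, count-weighted.
#'
#' @param reads reads data.frame.
#' @param categories factor from [annotate_reads()].
#' @return data.frame with `category`, `reads`, `fraction`.
#' @export
annotation_summary <- function(reads, categories) {
  if (!is.null(names(categories))) categories <- categories[reads$id]
  tot <- tapply(reads$count, categories, sum, default = 0L)
  data.frame(category = names(tot), reads = as.integer(tot),
             fraction = as.numeric(tot) / sum(reads$count),
             row.names = NULL)
}
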
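#' Attribute reads to TE consensus sequences ("consensus" method)
#'
#' A hit is a full-length, ungapped, end-to-end placement of the read (or
#' its reverse complement) within a consensus at Hamming distance at most
#' `max_mismatches` (default 3, tolerating divergence of genomic copies
#' from their consensus). Per read, the single best hit is reported:
#' fewest mismatches, ties broken by sense orientation first, then TE
#' name, then offset, so the choice is deterministic.
#'
#' @param reads reads data.frame (`id`, `seq`, `count`).
#' @param te_library consensus `DNAStringSet` with `te_class`/`te_family`
#'   metadata columns ([read_te_fasta()]).
#' @param max_mismatches maximum Hamming distance (default 3).
#' @return data.frame of TE hits: `read_id`, `te_name`, `te_class`,
#'   `te_family`, `orientation` (`sense`/`antisense` relative to the
#'   consensus), `offset` (1-based start within the consensus),
#'   `n_mismatches`, `method = "consensus"`. At most one row per read.
#' @export
consensus_map <- function(reads, te_library, max_mismatches = 3L) {
  stopifnot(length(te_library) > 0)
  info <- S4Vectors::mcols(te_library)
  te_names <- names(te_library)
  te_lens <- Biostrings::width(te_library)
  cat_f <- .concat_library(te_library)
  cat_r <- .concat_library(Biostrings::reverseComplement(te_library))
  scan <- function(pat, cat, orientation) {
    plen <- length(pat)
    m <- Biostrings::matchPattern(pat, cat$subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    starts <- IRanges::start(m)
    if (length(starts) == 0) return(NULL)
    seg <- findInterval(starts, cat$starts)
    inside <- seg >= 1 & starts >= cat$starts[seg] &
      starts + plen - 1L <= cat$ends[seg]
    starts <- starts[inside]
    seg <- seg[inside]
    if (length(starts) == 0) return(NULL)
    nmm <- Biostrings::neditStartingAt(pat, cat$subject,
                                       starting.at = starts,
                                       with.indels = FALSE)
    local <- starts - cat$starts[seg] + 1L
    offset <- if (orientation == "sense") local else
      te_lens[seg] - (local + plen - 1L) + 1L
    data.frame(te_idx = seg, offset = offset, nmm = nmm,
               orient_rank = if (orientation == "sense") 1L else 2L,
               orientation = orientation, stringsAsFactors = FALSE)
  }
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    pat <- Biostrings::DNAString(reads$seq[i])
    cand <- scan(pat, cat_f, "sense")
    # a 0-mismatch sense hit cannot be beaten (sense wins ties)
    if (is.null(cand) || min(cand$nmm) > 0L) {
      cand <- rbind(cand, scan(pat, cat_r, "antisense"))
    }
    if (is.null(cand) || nrow(cand) == 0) next
    # fewest mismatches, then sense before antisense, then name, offset
    o <- order(cand$nmm, cand$orient_rank, te_names[cand$te_idx],
               cand$offset)[1]
    b <- cand[o, ]
    rows[[i]] <- data.frame(
      read_id = reads$id[i], te_name = te_names[b$te_idx],
      te_class = info$te_class[b$te_idx],
      te_family = info$te_family[b$te_idx],
      orientation = b$orientation, offset = b$offset,
      n_mismatches = b$nmm, method = "consensus",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(), te_name = character(),
                      te_class = character(), te_family = character(),
                      orientation = character(), offset = integer(),
                      n_mismatches = integer(), method = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Attribute reads to repeat-masked genomic TE copies ("overlap" method)
#'
#' A hit is an exact, full-length occurrence of the read (or its reverse
#' complement) entirely inside a single repeat-masked interval's genomic
#' sequence; reads straddling a mask boundary do not hit. One hit per
#' read, taken from the first matching interval in (chrom, start) order.
#' The hit inherits the interval's TE identity; orientation is the match
#' strand relative to the masked copy's strand.
#'
#' @param reads reads data.frame.
#' @param masked masked-interval `GRanges` with `te_name`, `te_class`,
#'   `te_family` and strand ([read_repeatmasker_out()]).
#' @param genome named `DNAStringSet`.
#' @return data.frame of TE hits as in [consensus_map()] with
#'   `n_mismatches = 0` and `method = "overlap"`; `offset` is the 1-based
#'   match start within the masked interval (forward genomic coordinates).
#' @export
overlap_map <- function(reads, masked, genome) {
  ord <- order(as.character(GenomicRanges::seqnames(masked)),
               GenomicRanges::start(masked))
  masked <- masked[ord]
  chroms <- as.character(GenomicRanges::seqnames(masked))
  if (!all(chroms %in% names(genome))) {
    stop("masked interval on chromosome absent from genome")
  }
  if (any(GenomicRanges::end(masked) >
            vapply(chroms, function(c) length(genome[[c]]), numeric(1)))) {
    stop("masked interval outside genome bounds")
  }
  seqs <- lapply(seq_along(masked), function(i) {
    Biostrings::subseq(genome[[chroms[i]]],
                       GenomicRanges::start(masked)[i],
                       GenomicRanges::end(masked)[i])
  })
  mstrand <- as.character(GenomicRanges::strand(masked))
  rows <- vector("list", nrow(reads))
  unhit <- rep(TRUE, nrow(reads))
  for (t in seq_along(seqs)) {
    if (!any(unhit)) break
    idx <- which(unhit)
    fwd <- .exact_starts(reads$seq[idx], seqs[[t]])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$seq[idx])))
    rev <- .exact_starts(rc, seqs[[t]])
    copy_strand <- if (mstrand[t] == "-") "-" else "+"
    for (j in seq_along(idx)) {
      if (length(fwd[[j]]) > 0) {
        read_strand <- "+"
        off <- fwd[[j]][1]
      } else if (length(rev[[j]]) > 0) {
        read_strand <- "-"
        off <- rev[[j]][1]
      } else next
      i <- idx[j]
      unhit[i] <- FALSE
      orientation <- if (read_strand == copy_strand) "sense" else
        "antisense"
      rows[[i]] <- data.frame(
        read_id = reads$id[i], te_name = masked$te_name[t],
        te_class = masked$te_class[t], te_family = masked$te_family[t],
        orientation = orientation, offset = off, n_mismatches = 0L,
        method = "overlap", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(), te_name = character(),
                      te_class = character(), te_family = character(),
                      orientation = character(), offset = integer(),
                      n_mismatches = integer(), method = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate TE hits into class and family fractions
#'
#' Fractions over attributed reads, per TE class and per TE family,
#' optionally weighted by read multiplicity.
#'
#' @param hits hit table from one method.
#' @param reads optional reads data.frame supplying counts when
#'   `weight_by_count = TRUE`.
#' @param weight_by_count weight each hit by its read's library
#'   multiplicity (default FALSE).
#' @return list of two data.frames, `by_class` and `by_family`, each with
#'   a `fraction` column summing to 1 (empty when no hits).
#' @export
aggregate_by_te <- function(hits, reads = NULL, weight_by_count = FALSE) {
  if (nrow(hits) == 0) {
    e <- data.frame(level = character(), fraction = numeric())
    return(list(by_class = e, by_family = e))
  }
  w <- rep(1, nrow(hits))
  if (weight_by_count) {
    stopifnot(!is.null(reads))
    w <- reads$count[match(hits$read_id, reads$id)]
  }
  frac <- function(key) {
    key[is.na(key)] <- "Unknown"
    t <- tapply(w, key, sum)
    data.frame(level = names(t), fraction = as.numeric(t) / sum(w),
               row.names = NULL)
  }
  list(by_class = frac(hits$te_class), by_family = frac(hits$te_family))
}

#' Fraction of TE-derived reads antisense to their element
#'
#' @param hits hit table; must be non-empty.
#' @param reads optional reads for count weighting.
#' @param weight_by_count weight by multiplicity (default FALSE).
#' @return numeric fraction in `[0, 1]`.
#' @export
antisense_fraction <- function(hits, reads = NULL,
                               weight_by_count = FALSE) {
  if (nrow(hits) == 0) stop("no TE hits")
  w <- rep(1, nrow(hits))
  if (weight_by_count) {
    stopifnot(!is.null(reads))
    w <- reads$count[match(hits$read_id, reads$id)]
  }
  sum(w[hits$orientation == "antisense"]) / sum(w)
}

#' Genome-wide TE coverage by class, family and chromatin domain
#'
#' Base-pair union coverage (overlapping masked copies merged within each
#' group) as a fraction of total genome length, plus per-domain TE
#' coverage when chromatin domains are supplied.
#'
#' @param masked masked-interval `GRanges`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param domains optional domain `GRanges` with `class` column.
#' @return list with `total` (overall TE fraction), `by_class`,
#'   `by_family` data.frames, and `by_domain` (TE fraction of each
#'   chromatin class's bp) when domains are given.
#' @export
genome_te_landscape <- function(masked, chrom_lengths, domains = NULL) {
  genome_bp <- sum(as.numeric(chrom_lengths))
  union_bp <- function(gr) {
    if (length(gr) == 0) return(0)
    sum(as.numeric(IRanges::width(GenomicRanges::reduce(
      GenomicRanges::granges(gr), ignore.strand = TRUE))))
  }
  per_group <- function(key) {
    key[is.na(key)] <- "Unknown"
    groups <- sort(unique(key))
    data.frame(
      level = groups,
      fraction = vapply(groups, function(g)
        union_bp(masked[key == g]) / genome_bp, numeric(1)),
      row.names = NULL)
  }
  out <- list(total = union_bp(masked) / genome_bp,
              by_class = per_group(masked$te_class),
              by_family = per_group(masked$te_family))
  if (!is.null(domains)) {
    merged <- GenomicRanges::reduce(GenomicRanges::granges(masked),
                                    ignore.strand = TRUE)
    cls <- sort(unique(domains$class))
    out$by_domain <- data.frame(
      class = cls,
      fraction = vapply(cls, function(cl) {
        dom <- GenomicRanges::reduce(
          GenomicRanges::granges(domains[domains$class == cl]),
          ignore.strand = TRUE)
        dom_bp <- sum(as.numeric(IRanges::width(dom)))
        if (dom_bp == 0) return(0)
        sum(as.numeric(IRanges::width(GenomicRanges::intersect(
          dom, merged, ignore.strand = TRUE)))) / dom_bp
      }, numeric(1)),
      row.names = NULL)
  }
  out
}
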
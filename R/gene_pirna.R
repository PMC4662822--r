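#' Reads per million genome-mappers
#'
#' The normalisation used for genic piRNA abundance: read count divided by
#' the total number of genome-mapping piRNAs, times one million. Reported
#' to one decimal in tables.
#'
#' @param count read count.
#' @param total_genome_mappers library size (genome-mapping reads); must
#'   be positive.
#' @return numeric RPM.
#' @export
rpm <- function(count, total_genome_mappers) {
  if (any(total_genome_mappers <= 0)) stop("total_genome_mappers must be > 0")
  count / total_genome_mappers * 1e6
}

#' Spliced transcript sequence and coordinate maps
#'
#' @param tx a [transcript_model].
#' @param genome named `DNAStringSet`.
#' @return list with `seq` (DNAString, 5'->3' in transcript orientation),
#'   `tx_len`, `exon_starts_tx` (transcript coordinate of each exon's
#'   first base, in transcript order) and `utr3_tx` (transcript-coordinate
#'   c(start, end) of the 3'-UTR, or NULL).
#' @keywords internal
spliced_transcript <- function(tx, genome) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq) ||
      any(GenomicRanges::end(tx$exons) > length(chrom_seq))) {
    stop("transcript ", tx$transcript_id, ": exons outside genome")
  }
  pieces <- lapply(seq_along(tx$exons), function(i) {
    Biostrings::subseq(chrom_seq, GenomicRanges::start(tx$exons)[i],
                       GenomicRanges::end(tx$exons)[i])
  })
  fwd <- do.call(Biostrings::xscat, pieces)
  sseq <- if (tx$strand == "+") fwd else
    Biostrings::reverseComplement(fwd)
  widths <- IRanges::width(tx$exons)
  # transcript-order exons: genomic order for +, reversed for -
  ord <- if (tx$strand == "+") seq_along(widths) else rev(seq_along(widths))
  starts_tx <- cumsum(c(1L, widths[ord][-length(widths)]))
  utr3_tx <- NULL
  if (!is.null(tx$utr3)) {
    g1 <- GenomicRanges::start(tx$utr3)
    g2 <- GenomicRanges::end(tx$utr3)
    t1 <- genomic_to_tx(tx, g1)
    t2 <- genomic_to_tx(tx, g2)
    utr3_tx <- sort(c(t1, t2))
  }
  list(seq = sseq, tx_len = length(sseq), exon_order = ord,
       exon_starts_tx = starts_tx, utr3_tx = utr3_tx)
}

#' Map a genomic position to a transcript coordinate
#'
#' @param tx a [transcript_model].
#' @param gpos genomic position (must fall in an exon).
#' @return 1-based transcript coordinate from the 5' end.
#' @export
genomic_to_tx <- function(tx, gpos) {
  widths <- IRanges::width(tx$exons)
  ord <- if (tx$strand == "+") seq_along(widths) else rev(seq_along(widths))
  offset <- 0L
  for (i in ord) {
    s <- GenomicRanges::start(tx$exons)[i]
    e <- GenomicRanges::end(tx$exons)[i]
    if (gpos >= s && gpos <= e) {
      within <- if (tx$strand == "+") gpos - s else e - gpos
      return(offset + within + 1L)
    }
    offset <- offset + (e - s + 1L)
  }
  stop("position ", gpos, " not exonic in ", tx$transcript_id)
}

#' Map reads onto spliced transcript sequences
#'
#' Exact full-length (0-mismatch) matches of each read against the
#' spliced transcript sequence (sense) or its reverse complement
#' (antisense); the genic analyses of this package use genome-unique
#' reads and tolerate no mismatches. The leftmost match per read and
#' transcript is kept. Reads spanning an exon-exon junction match the
#' spliced sequence but no single genomic interval and are flagged.
#'
#' @param reads reads data.frame.
#' @param transcripts list of [transcript_model]s.
#' @param genome named `DNAStringSet`.
#' @return data.frame with one row per read x transcript match:
#'   `read_id`, `gene_id`, `transcript_id`, `orientation` (relative to
#'   the transcript), `tx_start`, `tx_end` (transcript coordinates of the
#'   match), `junction` (logical), `in_utr3` (logical; entire containment
#'   in the 3'-UTR, `NA` when the transcript has none).
#' @export
map_to_transcripts <- function(reads, transcripts, genome) {
  rows <- list()
  for (tx in transcripts) {
    sp <- spliced_transcript(tx, genome)
    rc <- Biostrings::reverseComplement(sp$seq)
    widths <- IRanges::width(tx$exons)[sp$exon_order]
    bounds <- cumsum(widths)  # transcript coord of each exon's last base
    exon_of <- function(p) findInterval(p - 1L, bounds) + 1L
    sense_hits <- .exact_starts(reads$seq, sp$seq)
    anti_hits <- .exact_starts(reads$seq, rc)
    for (i in seq_len(nrow(reads))) {
      # sense match preferred; one orientation per read per transcript
      if (length(sense_hits[[i]]) > 0) {
        orientation <- "sense"
        st <- sense_hits[[i]][1]
      } else if (length(anti_hits[[i]]) > 0) {
        orientation <- "antisense"
        st <- anti_hits[[i]][1]
      } else next
      plen <- nchar(reads$seq[i])
      en <- st + plen - 1L
      if (orientation == "antisense") {
        # express in transcript (sense) coordinates
        st2 <- sp$tx_len - en + 1L
        en <- sp$tx_len - st + 1L
        st <- st2
      }
      in_utr3 <- NA
      if (!is.null(sp$utr3_tx)) {
        in_utr3 <- st >= sp$utr3_tx[1] && en <= sp$utr3_tx[2]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$id[i], gene_id = tx$gene_id,
        transcript_id = tx$transcript_id, orientation = orientation,
        tx_start = st, tx_end = en,
        junction = exon_of(st) != exon_of(en),
        in_utr3 = in_utr3, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(), gene_id = character(),
                      transcript_id = character(),
                      orientation = character(), tx_start = integer(),
                      tx_end = integer(), junction = logical(),
                      in_utr3 = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' Fraction of a transcript's piRNAs entirely within its 3'-UTR
#'
#' Boundary-straddling reads count as outside (entire-containment rule).
#'
#' @param mapped rows of [map_to_transcripts()] output for one transcript.
#' @param reads optional reads for count weighting.
#' @param weighted weight by multiplicity (default TRUE).
#' @return numeric fraction, or `NA` when the transcript has no 3'-UTR.
#' @export
utr3_fraction <- function(mapped, reads = NULL, weighted = TRUE) {
  if (nrow(mapped) == 0) return(NA_real_)
  if (all(is.na(mapped$in_utr3))) return(NA_real_)
  w <- rep(1, nrow(mapped))
  if (weighted && !is.null(reads)) {
    w <- reads$count[match(mapped$read_id, reads$id)]
  }
  sum(w[mapped$in_utr3 %in% TRUE]) / sum(w)
}

#' Bin genes by unique-mapping piRNA RPM
#'
#' Groups 5-10, 10-50 and >50 RPM; boundaries half-open upward (an RPM of
#' exactly 10 belongs to the 10-50 group).
#'
#' @param rpm_values numeric RPM values.
#' @return factor with levels `below`, `g5_10`, `g10_50`, `g50plus`.
#' @export
rpm_group <- function(rpm_values) {
  cut(rpm_values, breaks = c(-Inf, 5, 10, 50, Inf),
      labels = c("below", "g5_10", "g10_50", "g50plus"),
      right = FALSE)
}

#' Length histogram separating siRNA and piRNA mass
#'
#' Gene-mapping small RNAs show a 21-nt siRNA peak alongside the 24-29 nt
#' piRNA population.
#'
#' @param reads reads data.frame (e.g. the reads mapped to one gene).
#' @param weighted weight by multiplicity (default TRUE).
#' @return list with `histogram` (data.frame length/count), `sirna21` and
#'   `pirna24_29` summary fractions.
#' @export
length_profile <- function(reads, weighted = TRUE) {
  len <- nchar(reads$seq)
  w <- if (weighted) reads$count else rep(1L, nrow(reads))
  t <- tapply(w, len, sum)
  hist <- data.frame(length = as.integer(names(t)),
                     count = as.numeric(t), row.names = NULL)
  tot <- sum(w)
  list(histogram = hist,
       sirna21 = if (tot > 0) sum(w[len == 21]) / tot else NA_real_,
       pirna24_29 = if (tot > 0)
         sum(w[len >= 24 & len <= 29]) / tot else NA_real_)
}

#' Per-transcript and per-gene piRNA profiles
#'
#' Aggregates transcript matches into the per-gene accounting used for
#' genic piRNA analysis: RPM of unique-mapping piRNAs, sense fraction,
#' 3'-UTR fraction, TE-matching RPM and RPM group. When a gene has
#' several transcripts its profile is that of the transcript with the
#' highest RPM.
#'
#' @param mapped output of [map_to_transcripts()].
#' @param reads reads data.frame (multiplicities used as weights).
#' @param total_genome_mappers RPM denominator (genome-mapping reads).
#' @param te_hits optional TE hit table from [consensus_map()] on the
#'   same reads, used for `te_matching_rpm`.
#' @return data.frame, one row per transcript, columns `gene_id`,
#'   `transcript_id`, `n_reads`, `rpm_unique`, `sense_fraction`,
#'   `utr3_fraction`, `te_matching_rpm`, `rpm_group`, plus logical
#'   `best_of_gene` marking the representative transcript per gene.
#' @export
gene_pirna_profiles <- function(mapped, reads, total_genome_mappers,
                                te_hits = NULL) {
  if (nrow(mapped) == 0) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      n_reads = numeric(), rpm_unique = numeric(),
                      sense_fraction = numeric(),
                      utr3_fraction = numeric(),
                      te_matching_rpm = numeric(),
                      rpm_group = factor(character(),
                        levels = c("below", "g5_10", "g10_50", "g50plus")),
                      best_of_gene = logical()))
  }
  te_ids <- if (is.null(te_hits)) character() else te_hits$read_id
  w_all <- reads$count[match(mapped$read_id, reads$id)]
  rows <- lapply(split(seq_len(nrow(mapped)), mapped$transcript_id),
                 function(idx) {
    m <- mapped[idx, , drop = FALSE]
    w <- w_all[idx]
    n <- sum(w)
    data.frame(
      gene_id = m$gene_id[1], transcript_id = m$transcript_id[1],
      n_reads = n,
      rpm_unique = rpm(n, total_genome_mappers),
      sense_fraction = sum(w[m$orientation == "sense"]) / n,
      utr3_fraction = utr3_fraction(m, reads),
      te_matching_rpm = rpm(sum(w[m$read_id %in% te_ids]),
                            total_genome_mappers),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rpm_group <- rpm_group(out$rpm_unique)
  out <- out[order(out$gene_id, -out$rpm_unique, out$transcript_id), ,
             drop = FALSE]
  out$best_of_gene <- !duplicated(out$gene_id)
  rownames(out) <- NULL
  out
}

#' Keep genes above a minimum piRNA RPM
#'
#' Strict inequality ("more than 0.5 RPM").
#'
#' @param profiles profile data.frame from [gene_pirna_profiles()].
#' @param min_rpm threshold (default 0.5).
#' @return the retained rows.
#' @export
filter_genes_by_rpm <- function(profiles, min_rpm = 0.5) {
  profiles[profiles$rpm_unique > min_rpm, , drop = FALSE]
}

#' Flag TE-contaminated transcripts and clean the genic read set
#'
#' A transcript is flagged when the RPM of its reads that also hit a TE
#' consensus (0-3 mismatches) exceeds `min_te_rpm`. Independently of the
#' flag, every read mapping to both a transcript and a TE is removed from
#' the cleaned set used for downstream genic statistics.
#'
#' @param mapped output of [map_to_transcripts()].
#' @param reads reads data.frame.
#' @param te_hits TE hit table from [consensus_map()] on the same reads.
#' @param total_genome_mappers RPM denominator.
#' @param min_te_rpm flag threshold (default 0.5).
#' @return list with `flagged` (character vector of transcript ids) and
#'   `cleaned` (the `mapped` rows whose reads hit no TE).
#' @export
te_contamination_filter <- function(mapped, reads, te_hits,
                                    total_genome_mappers,
                                    min_te_rpm = 0.5) {
  te_ids <- te_hits$read_id
  dual <- mapped$read_id %in% te_ids
  w <- reads$count[match(mapped$read_id, reads$id)]
  te_rpm <- tapply(w * dual, mapped$transcript_id, sum)
  te_rpm <- rpm(te_rpm, total_genome_mappers)
  list(flagged = names(te_rpm)[te_rpm > min_te_rpm],
       cleaned = mapped[!dual, , drop = FALSE])
}
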
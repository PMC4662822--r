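#' 5' end position of each alignment
#'
#' The biologically defined piRNA position is its 5' end: the leftmost base
#' for a plus-strand placement, the rightmost base for a minus-strand one.
#'
#' @param alignments alignment `GRanges`.
#' @return integer vector of 1-based 5'-end coordinates.
#' @export
five_prime_pos <- function(alignments) {
  ifelse(as.character(GenomicRanges::strand(alignments)) == "-",
         GenomicRanges::end(alignments),
         GenomicRanges::start(alignments))
}

#' Bin genome-unique alignments into fixed windows
#'
#' Non-overlapping windows of `window_size` bp anchored at coordinate 1;
#' each alignment is assigned to the single window containing its 5' end.
#' Only windows with at least one read are materialised (absent windows
#' are logically zero).
#'
#' @param alignments alignment `GRanges` (intended: the collapsed
#'   genome-unique stratum).
#' @param window_size window width in bp (default 5000).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   alignments beyond a declared length are an error.
#' @return data.frame with `chrom`, `index` (0-based window index),
#'   `start`, `end` (1-based closed window interval), `count_plus`,
#'   `count_minus`.
#' @export
bin_to_windows <- function(alignments, window_size = 5000L,
                           chrom_lengths = NULL) {
  if (length(alignments) == 0) {
    return(data.frame(chrom = character(), index = integer(),
                      start = integer(), end = integer(),
                      count_plus = integer(), count_minus = integer()))
  }
  stopifnot(window_size > 0)
  chrom <- as.character(GenomicRanges::seqnames(alignments))
  pos5 <- five_prime_pos(alignments)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[chrom]
    if (any(is.na(lim)) || any(GenomicRanges::end(alignments) > lim)) {
      stop("alignment beyond declared chromosome length")
    }
  }
  idx <- (pos5 - 1L) %/% as.integer(window_size)
  minus <- as.character(GenomicRanges::strand(alignments)) == "-"
  key <- paste(chrom, idx)
  agg <- function(sel) {
    t <- table(factor(key[sel], levels = unique(key)))
    as.integer(t)
  }
  ukey <- unique(key)
  first <- match(ukey, key)
  out <- data.frame(
    chrom = chrom[first],
    index = idx[first],
    count_plus = agg(!minus),
    count_minus = agg(minus),
    stringsAsFactors = FALSE)
  out$start <- out$index * as.integer(window_size) + 1L
  out$end <- (out$index + 1L) * as.integer(window_size)
  out <- out[order(out$chrom, out$index),
             c("chrom", "index", "start", "end", "count_plus",
               "count_minus")]
  rownames(out) <- NULL
  out
}

#' Library-size-scaled minimum cluster total
#'
#' The minimum total piRNAs for a candidate cluster is a fixed fraction of
#' the genome-unique library size, rounded down: 0.05 % of 568,080
#' uniquely mapping piRNAs gives 284; 0.05 % of 202,533 gives 101.
#'
#' @param n_unique_mappers number of genome-unique piRNAs in the library.
#' @param fraction fraction of the library (default 0.0005, i.e. 0.05 %).
#' @return integer threshold, `floor(fraction * n_unique_mappers)`.
#' @export
min_total_threshold <- function(n_unique_mappers, fraction = 0.0005) {
  if (n_unique_mappers < 0) stop("n_unique_mappers must be >= 0")
  as.integer(floor(fraction * n_unique_mappers))
}

#' Call piRNA clusters from window counts
#'
#' A cluster is a maximal run of windows that begins and ends on a
#' qualifying window (total count >= `min_per_window`), in which every
#' maximal internal run of sub-threshold windows is at most
#' `max_gap_windows` long (with 5-kb windows and the default gap of 4,
#' gaps span at most 20 kb). Candidates are kept when the summed read
#' count over the whole span (qualifying and internal gap windows alike)
#' reaches `min_total`. Cluster intervals are trimmed to the first and
#' last qualifying window; clusters never cross chromosomes.
#'
#' @param windows window data.frame from [bin_to_windows()].
#' @param min_per_window minimum unique piRNAs for a qualifying window
#'   (default 10).
#' @param max_gap_windows maximum run of sub-threshold windows allowed
#'   inside a cluster (default 4).
#' @param min_total minimum summed piRNAs per cluster, typically from
#'   [min_total_threshold()] (default 0 = no total filter).
#' @return a `GRanges` of clusters sorted by position, with metadata
#'   columns `n_unique_pirnas`, `count_plus`, `count_minus`.
#' @export
call_clusters <- function(windows, min_per_window = 10L,
                          max_gap_windows = 4L, min_total = 0L) {
  stopifnot(min_per_window >= 1L, max_gap_windows >= 0L)
  empty <- GenomicRanges::GRanges()
  empty$n_unique_pirnas <- integer()
  empty$count_plus <- integer()
  empty$count_minus <- integer()
  if (nrow(windows) == 0) return(empty)
  wsize <- windows$end[1] - windows$start[1] + 1L
  out <- list()
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    w <- w[order(w$index), , drop = FALSE]
    total <- w$count_plus + w$count_minus
    q <- w$index[total >= min_per_window]
    if (length(q) == 0) next
    # split qualifying windows into runs: successive qualifying windows
    # stay in one run when separated by <= max_gap_windows sub-threshold
    # windows (all intervening windows are sub-threshold by construction)
    brk <- c(0L, cumsum(diff(q) - 1L > max_gap_windows))
    for (run in split(q, brk)) {
      first <- run[1]
      last <- run[length(run)]
      span <- w$index >= first & w$index <= last
      n_total <- sum(total[span])
      if (n_total < min_total) next
      gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = first * wsize + 1L,
                                  end = (last + 1L) * wsize))
      gr$n_unique_pirnas <- n_total
      gr$count_plus <- sum(w$count_plus[span])
      gr$count_minus <- sum(w$count_minus[span])
      out[[length(out) + 1L]] <- gr
    }
  }
  if (length(out) == 0) return(empty)
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Strand-bias classification of clusters
#'
#' A cluster with more than 75 % of its piRNAs on one genomic strand has
#' a strong bias; more than 90 % is a near-exclusive bias (both strict
#' inequalities, "more than"). Strand-biased clusters are interpreted as
#' uni-directionally transcribed, unbiased ones as bidirectional.
#'
#' @param clusters cluster `GRanges` with `count_plus`/`count_minus`, as
#'   from [call_clusters()].
#' @return the input with added metadata columns `dominant_fraction`,
#'   `bias_class` (`unbiased`/`strong`/`near_exclusive`) and
#'   `dominant_strand` (`+`, `-`, or `none` on an exact tie).
#' @export
classify_strand_bias <- function(clusters) {
  if (length(clusters) == 0) {
    clusters$dominant_fraction <- numeric()
    clusters$bias_class <- character()
    clusters$dominant_strand <- character()
    return(clusters)
  }
  n <- clusters$count_plus + clusters$count_minus
  if (any(n <= 0)) stop("cluster with no piRNAs")
  frac <- pmax(clusters$count_plus, clusters$count_minus) / n
  clusters$dominant_fraction <- frac
  clusters$bias_class <- ifelse(frac > 0.90, "near_exclusive",
                                ifelse(frac > 0.75, "strong", "unbiased"))
  clusters$dominant_strand <- ifelse(
    clusters$count_plus == clusters$count_minus, "none",
    ifelse(clusters$count_plus > clusters$count_minus, "+", "-"))
  clusters
}

.chromatin_priority <- c("pericentromeric", "intercalary_diffuse",
                         "intercalary_compact", "euchromatic")

#' Assign each cluster to a chromatin domain
#'
#' The class with the largest base-pair overlap wins; ties break toward
#' the more heterochromatic class (pericentromeric > intercalary diffuse >
#' intercalary compact > euchromatic). Clusters overlapping no domain are
#' `unassigned`. Domains of different classes must not overlap.
#'
#' @param clusters cluster `GRanges`.
#' @param domains domain `GRanges` with a `class` metadata column (see
#'   [read_domains_bed()]).
#' @return the clusters with an added `chromatin_class` column.
#' @export
assign_chromatin <- function(clusters, domains) {
  cls <- domains$class
  stopifnot(all(cls %in% .chromatin_priority))
  # overlapping domains of different classes are ambiguous
  ov <- GenomicRanges::findOverlaps(domains, domains,
                                    ignore.strand = TRUE)
  bad <- S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov) &
    cls[S4Vectors::queryHits(ov)] != cls[S4Vectors::subjectHits(ov)]
  if (any(bad)) stop("overlapping chromatin domains of different classes")
  if (length(clusters) == 0) {
    clusters$chromatin_class <- character()
    return(clusters)
  }
  hit <- GenomicRanges::findOverlaps(clusters, domains,
                                     ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  ow <- IRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(clusters)[qh],
    GenomicRanges::granges(domains)[sh], ignore.strand = TRUE))
  # bp overlap per cluster x class; which.max takes the first class in
  # priority order on ties
  bp <- tapply(ow, list(factor(qh, levels = seq_along(clusters)),
                        factor(cls[sh], levels = .chromatin_priority)),
               sum, default = 0)
  bp[is.na(bp)] <- 0
  clusters$chromatin_class <- unname(apply(bp, 1, function(row) {
    if (all(row == 0)) "unassigned" else
      .chromatin_priority[which.max(row)]
  }))
  clusters
}

#' TE content of each cluster
#'
#' Fraction of cluster base pairs covered by the union of repeat-masked
#' intervals (overlapping masked copies are merged before coverage).
#'
#' @param clusters cluster `GRanges`.
#' @param masked masked-interval `GRanges` (see [read_repeatmasker_out()]).
#' @return the clusters with an added numeric `te_content` column in
#'   `[0, 1]`.
#' @export
cluster_te_content <- function(clusters, masked) {
  if (length(clusters) == 0) {
    clusters$te_content <- numeric()
    return(clusters)
  }
  merged <- GenomicRanges::reduce(GenomicRanges::granges(masked),
                                  ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(
    GenomicRanges::granges(clusters), merged, ignore.strand = TRUE)
  covered <- vapply(seq_along(clusters), function(i) {
    hit <- IRanges::subsetByOverlaps(ov, clusters[i], ignore.strand = TRUE)
    sum(IRanges::width(hit))
  }, numeric(1))
  clusters$te_content <- covered / IRanges::width(clusters)
  clusters
}

#' Share of unique piRNAs produced per chromatin class and outside clusters
#'
#' Each genome-unique alignment is attributed by its 5'-end position to
#' the (disjoint) cluster containing it, then summed by the cluster's
#' chromatin class; reads in no cluster are `outside_clusters`. Fractions
#' sum to one.
#'
#' @param clusters cluster `GRanges` with `chromatin_class` (from
#'   [assign_chromatin()]); pairwise disjoint.
#' @param alignments the unique-mapper alignment `GRanges` used for
#'   cluster calling.
#' @return data.frame with `class` and `fraction` over
#'   `pericentromeric, intercalary_diffuse, intercalary_compact,
#'   euchromatic, unassigned, outside_clusters`.
#' @export
production_shares <- function(clusters, alignments) {
  lev <- c(.chromatin_priority, "unassigned", "outside_clusters")
  n <- length(alignments)
  if (n == 0) stop("no alignments")
  pos <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(alignments),
    ranges = IRanges::IRanges(start = five_prime_pos(alignments),
                              width = 1L))
  lab <- rep("outside_clusters", n)
  if (length(clusters) > 0) {
    ov <- GenomicRanges::findOverlaps(pos, clusters, ignore.strand = TRUE)
    lab[S4Vectors::queryHits(ov)] <-
      clusters$chromatin_class[S4Vectors::subjectHits(ov)]
  }
  tab <- table(factor(lab, levels = lev))
  data.frame(class = lev, fraction = as.numeric(tab) / n,
             row.names = NULL)
}

#' Rank clusters by unique-piRNA production
#'
#' Descending by `n_unique_pirnas`; ties break by chromosome name then
#' start coordinate for determinism.
#'
#' @param clusters cluster `GRanges`.
#' @param top_n optionally keep only the top n (default all).
#' @return the ranked clusters with an integer `rank` column (1 = most
#'   productive).
#' @export
rank_clusters <- function(clusters, top_n = Inf) {
  if (length(clusters) == 0) {
    clusters$rank <- integer()
    return(clusters)
  }
  o <- order(-clusters$n_unique_pirnas,
             as.character(GenomicRanges::seqnames(clusters)),
             GenomicRanges::start(clusters))
  out <- clusters[o]
  out$rank <- seq_along(out)
  utils::head(out, n = if (is.finite(top_n)) top_n else length(out))
}

#' Tabular cluster report
#'
#' One row per cluster with coordinates, counts, strand bias, TE content
#' and chromatin class, in rank order.
#'
#' @param clusters a fully annotated, ranked cluster `GRanges`.
#' @return a data.frame ready to write as TSV.
#' @export
cluster_report <- function(clusters) {
  df <- data.frame(
    rank = clusters$rank,
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters),
    end = GenomicRanges::end(clusters),
    n_unique_pirnas = clusters$n_unique_pirnas,
    count_plus = clusters$count_plus,
    count_minus = clusters$count_minus,
    dominant_fraction = clusters$dominant_fraction,
    bias_class = clusters$bias_class,
    dominant_strand = clusters$dominant_strand,
    stringsAsFactors = FALSE)
  if (!is.null(clusters$te_content)) df$te_content <- clusters$te_content
  if (!is.null(clusters$chromatin_class))
    df$chromatin_class <- clusters$chromatin_class
  df[order(df$rank), , drop = FALSE]
}
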
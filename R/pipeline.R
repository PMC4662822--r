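#' Default analysis configuration
#'
#' All parameters of the pipeline in one list, with defaults frozen to
#' the reference protocol: 5-kb windows, a minimum of 10 unique piRNAs
#' per qualifying window, gaps of up to 4 contiguous sub-threshold
#' windows (20 kb), a cluster total of 0.05 % of the unique-mapper
#' library, strand-bias thresholds of 75 % and 90 %, up to 3 mismatches
#' for TE consensus attribution, a 0.5 RPM genic filter, the 24-29 nt
#' piRNA size range and a 30-nt maximum ping-pong offset.
#'
#' @param ... overrides of any default, e.g. `window_size = 1000`.
#' @return a named list of parameters with class `pirnascan_config`; the
#'   attribute `config_hash` identifies the parameter set.
#' @export
pirnascan_config <- function(...) {
  cfg <- list(
    window_size = 5000L,
    min_per_window = 10L,
    max_gap_windows = 4L,
    cluster_fraction = 0.0005,
    bias_strong = 0.75,
    bias_near_exclusive = 0.90,
    max_mismatches = 3L,
    min_rpm = 0.5,
    rpm_bins = c(5, 10, 50),
    size_min = 24L,
    size_max = 29L,
    k_max = 30L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "pirnascan_config"
  attr(cfg, "config_hash") <- paste0(
    "cfg", format(sum(utils::head(
      as.integer(charToRaw(paste(deparse(unclass(cfg)), collapse = ""))),
      1e4) * seq_len(min(1e4, nchar(paste(deparse(unclass(cfg)),
                                          collapse = "")))) %% 1e8)))
  cfg
}

#' Run the full analysis on reads and alignments
#'
#' Executes the stages in order: library stratification and size
#' filtering, window binning and cluster calling on the collapsed
#' genome-unique stratum, strand-bias / chromatin / TE-content
#' annotation of clusters, piRNA production shares, TE attribution by
#' both methods with class/family aggregation and signature statistics,
#' the ping-pong overlap histogram, and per-gene piRNA profiles.
#' Optional inputs switch the corresponding stage off when absent.
#'
#' @param reads reads data.frame ([read_small_rna_fasta()]).
#' @param alignments alignment `GRanges` ([read_alignments_bed()] or
#'   [map_reads_exact()]).
#' @param config a [pirnascan_config()].
#' @param te_library optional consensus `DNAStringSet`.
#' @param masked optional masked-interval `GRanges`.
#' @param genome optional `DNAStringSet` (needed for the overlap method
#'   and genic mapping).
#' @param transcripts optional list of [transcript_model]s.
#' @param domains optional chromatin-domain `GRanges`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return a list bundle: `config`, `strata`, `windows`, `clusters`
#'   (annotated, ranked `GRanges`), `cluster_table`, `shares`,
#'   `te_consensus_hits`, `te_overlap_hits`, `te_fractions`,
#'   `te_signatures`, `antisense_fraction`, `pingpong`,
#'   `gene_profiles`.
#' @export
run_pipeline <- function(reads, alignments, config = pirnascan_config(),
                         te_library = NULL, masked = NULL, genome = NULL,
                         transcripts = NULL, domains = NULL,
                         chrom_lengths = NULL) {
  pir <- size_filter(reads, config$size_min, config$size_max)
  al <- alignments[alignments$read_id %in% pir$id]
  strata <- build_strata(pir, al)
  out <- list(config = config, strata = strata)

  # clusters on the collapsed unique stratum
  cu <- strata$CU
  windows <- bin_to_windows(cu$alignments, config$window_size,
                            chrom_lengths)
  min_total <- min_total_threshold(nrow(cu$reads),
                                   config$cluster_fraction)
  clusters <- call_clusters(windows, config$min_per_window,
                            config$max_gap_windows, min_total)
  clusters <- classify_strand_bias(clusters)
  if (!is.null(domains)) clusters <- assign_chromatin(clusters, domains)
  if (!is.null(masked)) clusters <- cluster_te_content(clusters, masked)
  clusters <- rank_clusters(clusters)
  out$windows <- windows
  out$min_total <- min_total
  out$clusters <- clusters
  out$cluster_table <- cluster_report(clusters)
  if (!is.null(domains) && length(clusters) > 0) {
    out$shares <- production_shares(clusters, cu$alignments)
  }

  # TE attribution on the full piRNA-sized library
  if (!is.null(te_library)) {
    hits_c <- consensus_map(pir, te_library, config$max_mismatches)
    out$te_consensus_hits <- hits_c
    out$te_fractions <- aggregate_by_te(hits_c, pir,
                                        weight_by_count = TRUE)
    if (nrow(hits_c) > 0) {
      out$antisense_fraction <- antisense_fraction(hits_c, pir,
                                                   weight_by_count = TRUE)
      out$te_signatures <- te_signature_table(hits_c, pir)
    }
  }
  if (!is.null(masked) && !is.null(genome)) {
    out$te_overlap_hits <- overlap_map(pir, masked, genome)
    if (!is.null(chrom_lengths)) {
      out$te_landscape <- genome_te_landscape(masked, chrom_lengths,
                                              domains)
    }
  }

  # ping-pong signature on all piRNA-sized alignments
  out$pingpong <- ping_pong_histogram(
    al, stats::setNames(pir$count, pir$id), config$k_max)

  # genic piRNAs on the non-collapsed unique stratum
  if (!is.null(transcripts) && length(transcripts) > 0 &&
      !is.null(genome)) {
    ncu <- strata$NCU
    mapped <- map_to_transcripts(ncu$reads, transcripts, genome)
    total <- strata$NCNU$total_reads
    prof <- gene_pirna_profiles(
      mapped, ncu$reads, total,
      te_hits = if (!is.null(te_library)) out$te_consensus_hits)
    out$gene_mapped <- mapped
    out$gene_profiles <- filter_genes_by_rpm(prof, config$min_rpm)
  }
  out
}
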
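---
title: "Methods: piRNA clusters, transposon attribution and ping-pong signatures"
author: "pirnascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA clusters, transposon attribution and ping-pong signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascan)
```

# The analysis

PIWI-interacting RNAs (piRNAs) are 24–30 nt germline small RNAs that
guide the silencing of transposable elements (TEs). Most piRNAs derive
from discrete genomic loci — piRNA clusters — and from two secondary
sources: genomic TE copies and the 3′-UTRs of protein-coding
transcripts. `pirnascan` implements the standard ovarian small-RNA
workflow for characterising this population:

1. **Library stratification.** The sequenced library is reduced to three
   strata. *NCNU* (non-collapsed, non-unique) keeps every read with any
   genomic placement and is used for TE attribution; *NCU* (non-collapsed
   unique) keeps only reads mapping to a single genomic locus and is
   used for genic analysis; *CU* (collapsed unique) reduces the NCU
   stratum to distinct sequences and is the input for cluster calling.
   The size filter retains 24–29 nt reads, the broad secondary peak of
   the bimodal length distribution whose apex sits at 27 nt (the 22-nt
   peak is miRNA).

2. **Cluster calling.** Genome-unique piRNA 5′ ends are binned into
   fixed, non-overlapping 5-kb windows anchored at coordinate 1. A
   window *qualifies* with ≥ 10 unique piRNAs. A cluster is a maximal
   run of windows that starts and ends on a qualifying window and whose
   internal sub-threshold gaps are each at most 4 windows (20 kb) long.
   A candidate survives if its total read count reaches 0.05 % of the
   unique-mapper library (`floor(0.0005 × n)`; 568,080 unique mappers
   give 284, 202,533 give 101).

3. **Cluster annotation.** A cluster with > 75 % of piRNAs on one
   genomic strand has a *strong* bias and is interpreted as
   uni-directionally transcribed; > 90 % is *near-exclusive*; both
   thresholds are strict. Each cluster is assigned the chromatin domain
   (pericentromeric, diffuse or compact intercalary heterochromatin,
   euchromatin) with the largest base-pair overlap, its TE content is
   the union coverage of repeat-masked intervals, and piRNA production
   shares are tallied per domain and outside clusters.

4. **TE attribution, two ways.** The *consensus* method places each
   read (or its reverse complement) end-to-end within a TE consensus at
   Hamming distance ≤ 3, reporting the single best hit with
   deterministic tie-breaks (fewest mismatches, sense before antisense,
   then name and offset). The *overlap* method requires an exact,
   full-length occurrence of the read inside a single repeat-masked
   genomic interval, inheriting that copy's identity; reads straddling
   a mask boundary do not count. The two methods answer different
   questions — proximity to the ancestral element versus presence in an
   extant genomic copy — and their outputs are never merged.

5. **Signatures.** The 1U bias (uridine at position 1, antisense and
   primary piRNAs) and 10A bias (adenine at position 10, sense and
   secondary piRNAs) are positional base fractions. The ping-pong
   amplification cycle cleaves the complementary RNA between positions
   10 and 11, so the 5′ ends of complementary piRNA pairs overlap by
   exactly 10 nt: for a plus-strand 5′ end at p and a minus-strand 5′
   end at q the overlap is k = q − p + 1, and the histogram of k over
   all opposite-strand 5′-end pairs peaks at 10 in a ping-pong-active
   tissue. A z-score (`z10`) compares the k = 10 weight against offsets
   1–30 excluding 10.

6. **Genic piRNAs.** Unique-mapper reads are matched exactly against
   spliced transcript sequences; per transcript the package reports RPM
   (reads per million genome-mappers), the sense-strand fraction, the
   fraction of reads entirely contained in the 3′-UTR, and TE-matching
   RPM. Genes pass at RPM > 0.5 (strict) and are binned into the 5–10,
   10–50 and > 50 RPM groups.

# Parameters that matter

| parameter | default | role |
|---|---|---|
| `window_size` | 5000 bp | cluster-calling bin width |
| `min_per_window` | 10 reads | qualifying-window threshold |
| `max_gap_windows` | 4 | longest tolerated sub-threshold gap |
| `cluster_fraction` | 0.0005 | minimum cluster total as a library fraction |
| `bias_strong`, `bias_near_exclusive` | 0.75, 0.90 | strand-bias classes (strict) |
| `max_mismatches` | 3 | consensus-method Hamming budget |
| `min_rpm` | 0.5 | genic piRNA filter (strict) |
| `size_min`–`size_max` | 24–29 nt | piRNA size range |
| `k_max` | 30 | largest ping-pong offset tabulated |

All defaults live in `pirnascan_config()`; any override is carried in
the returned object and reflected in its hash.

# Numerical and design choices

Several points are under-determined by the protocol; the package fixes
them as follows and documents each as its own choice.

* **Coordinates.** All internal coordinates are 1-based closed
  `GRanges`; BED input/output converts at the boundary (rtracklayer),
  GFF3 and RepeatMasker `.out` pass through unchanged. One internal
  convention confines off-by-one risks to the I/O layer.
* **Window anchoring and read position.** Windows are phased at
  coordinate 1; a read belongs to the window containing its 5′ end (the
  biologically defined piRNA position, also used by the ping-pong
  statistic). For a minus-strand read the 5′ end is its rightmost base.
* **Threshold rounding.** The cluster minimum uses `floor`, which
  reproduces both published worked values (284 and 101).
* **Gap counting.** Sub-threshold windows inside a cluster span
  contribute their reads to the cluster total; gaps may not sit at a
  cluster edge (spans are trimmed to qualifying windows). Single-window
  clusters are allowed if they pass the total threshold.
* **Tie-breaks.** Equal strand counts give `dominant_strand = "none"`;
  chromatin ties resolve toward the more heterochromatic class;
  consensus-method ties resolve sense-first, then name, then offset;
  ranking ties resolve by chromosome then start.
* **Genic matching.** Transcript matching allows 0 mismatches (the
  genic analyses use genome-unique reads; the TE cross-check reuses the
  ≤ 3-mismatch consensus mapper). 3′-UTR membership requires entire
  containment — boundary-straddling reads count outside. When a gene
  has several transcripts, the gene-level profile is the transcript
  with the highest RPM.
* **RPM groups.** Half-open upward: RPM 10 belongs to 10–50.
* **Ping-pong weighting.** Two modes are implemented because the
  normalisation of the published histogram is not stated: `"reads"`
  (default; distinct reads with ≥ 1 partner at each offset) and
  `"pairs"` (multiplicity-weighted 5′-pair products).
* **Strand-swap symmetry.** The histogram's indifference to which
  strand is called "plus" holds for a strand relabel combined with a
  coordinate reflection (which maps every 5′–5′ pair to one of the same
  overlap); a bare flag swap would turn 5′-facing pairs into 3′-facing
  ones.

# The synthetic landscape

`sim_spec()` / `build_genome()` / `simulate_reads()` generate a
two-chromosome (250 kb + 200 kb) genome with planted ground truth, so
every stage is testable without downloads. The defaults are the
package's reference study conditions:

* three clusters aligned to window boundaries — near-exclusive
  (bias 0.95) in pericentromeric heterochromatin, unbiased (0.55) in
  diffuse intercalary heterochromatin, strong (0.85) in euchromatin —
  with 1500/1000/1200 reads;
* a three-element consensus library (LTR/Gypsy 1200 bp, LINE/CR1
  1000 bp, DNA/Mariner 800 bp) with six planted copies at 5 %
  divergence, four of them read-producing and located inside clusters
  (as TE-derived piRNAs overwhelmingly are); per producing copy 150
  antisense primaries, a 0.30 ping-pong pairing fraction and 22
  independent sense reads, which yields the canonical ~69 % antisense
  fraction among TE piRNAs;
* read lengths 24–29 nt with the apex at 27; a 0.79 probability of 5′ U
  on cluster and primary reads and 0.54 of position-10 A on independent
  sense reads;
* three two-or-one-exon genes with 330 sense and 70 antisense reads
  each (82.5 % sense), concentrated in the 3′-UTR with weight 0.58;
* 300 miRNA reads (22 nt, five loci) and a Poisson background of 0.2
  reads per 5-kb window.

Biases are planted by *conditional 5′-position selection*: a read that
should start with U is placed at a position whose genomic base already
is T, so every simulated read is an exact substring of the genome. This
keeps the zero-divergence method-consistency property exact (overlap
and 0-mismatch consensus attribution agree read-for-read) and means
1U/10A statistics are genuine properties of the emitted sequences, not
post-hoc edits. Each ping-pong secondary is placed at exactly a 10-nt
5′ overlap with its primary, so its position-10 base is the complement
of the primary's position-1 base by construction.

TE and genic reads concentrate their multiplicity on a small set of 5′
hotspots (8 primary + 4 sense per TE copy; 4 sense + 2 antisense per
gene), as collapsed libraries do. The hotspot counts are deliberately
kept below the 10-distinct-reads-per-window qualifying threshold so
that genic and background loci never masquerade as clusters and
zero-false-positive recovery tests are meaningful. Genic reads are
sampled within single exons; junction-spanning matching is exercised by
hand-built transcripts in the test-suite instead.

What the generator does **not** emulate: sequencing error and quality
realism, adapter contamination, gapped TE divergence (substitutions
only), multi-mapping arising from dispersed repeat families (copies are
independently diverged), and transcript-abundance-coupled genic read
counts. Passing recovery tests therefore demonstrates the correctness
of the algorithms under clean conditions, not robustness to every
artefact of real libraries; on real data the gapped-alignment consensus
counts of a seed-and-extend aligner may differ slightly from the
ungapped Hamming search used here.

# Problem sizes and determinism

The reference landscape holds roughly 4,800 distinct reads (~6,100 with
multiplicities); the full pipeline runs in about a minute and the
recovery suite re-uses one shared simulation. The ping-pong acceptance
computation uses 12,000 primary reads with full pairing. The
brute-force cross-checks run 500 random window vectors (length ≤ 200)
against an independent enumeration of the gap rule, and an exhaustive
all-offset Hamming search over small consensus libraries. All
randomness flows from a single integer seed (R's Mersenne-Twister);
`build_genome()` consumes `seed` and `simulate_reads()` consumes
`seed + 1`, and identical spec + seed give byte-identical FASTQ/BED/TSV
outputs.

# Known limitations

* The internal exact mapper (`map_reads_exact()`) is intended for
  synthetic genomes; real assemblies should come with precomputed BED
  alignments.
* The consensus method is an ungapped Hamming search; indel-diverged
  copies are found only via the overlap method.
* Chromatin classification requires a user-supplied domain BED; the
  package does not infer chromatin state.
* Production shares attribute a read by its 5′ end, so a read whose 5′
  end falls just outside a cluster is "outside" even if most of its
  body overlaps.
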
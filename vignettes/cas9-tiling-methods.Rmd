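---
title: "Cas9 tiling panel design and evaluation: methods"
author: "castile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cas9 tiling panel design and evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castile)
```

## The problem

CRISPR/Cas9-mediated target enrichment excises a genomic fragment with two
flanking guide RNAs and feeds it, amplification-free, to a nanopore
sequencer. Single excisions are practical up to a few tens of kbp; beyond
that, the region of interest (ROI) must be *tiled*: partitioned into
overlapping sub-regions (sub-ROIs) of roughly 50 kbp, each excised by its
own guide pair, so that the full ROI — here on the order of 250 kbp — can be
enriched, sequenced and de-novo assembled as a single contig. `castile`
implements the desk half of this workflow: guide enumeration and
filtering, tiling and reaction-pool design, enrichment QC, and comparison
of the resulting assembly against a reference. A seeded simulator makes
every step testable without external data.

## Coordinates

Every interval inside the package is 0-based half-open; every user-facing
string or report is 1-based inclusive, the dialect of genome browsers and
publication tables. The conversion happens exactly once, at the format
boundary (`parse_region_string()`, `format_region_string()`, the file
readers and the report writers), which removes off-by-one ambiguity from
the internal arithmetic. Minus-strand guides are *reported* with start >
end — coordinates read 5'→3' along the minus strand, the convention of
published crRNA tables — but stored as a normalised interval plus strand
flag.

## Guide design

`scan_protospacers()` enumerates every 20-nt window on both strands whose
adjacent trinucleotide matches the PAM (IUPAC pattern, default `NGG` for
SpCas9). Windows containing N are excluded, and N in the reference is
never matched by any pattern symbol; ambiguity codes other than N are
rejected at load since no downstream rule is defined over them.

The blunt cut is placed 3 bp 5' of the PAM, between protospacer positions
17 and 18 — the canonical SpCas9 geometry. `cut_position` is the 0-based
coordinate of the last base retained on the left of the cut. This single
convention, combined with *truncating* (not rounding) fragment lengths to
0.1 kbp in reports, is what reproduces published sub-ROI length tables
from printed guide coordinates; rounding would not (48,663 bp must print
as 48.6).

`filter_candidates()` applies four locus criteria, each kept as an
explicit flag so that non-passing candidates remain visible for review:

* **in_gene** — the protospacer+PAM footprint lies inside a gene/CDS
  feature. Coding regions are preferred cut sites because they are more
  conserved than intergenic sequence, so the guide is less likely to
  mismatch the (unsequenced) target cultivar.
* **covered** — every footprint base reaches `min_depth` (default 5) in
  short-read data from the target individual. The footprint is the full
  23 bp including the PAM: the paper trail for whether the PAM belongs in
  the footprint is ambiguous, and including it is the conservative
  choice.
* **variant_free** — no known SNV/indel overlaps the footprint; a
  mismatch between guide and target DNA can abolish cutting.
* **unique** — `count_genomic_matches()` finds exactly one genome-wide
  site. The screen is an exhaustive scan with a configurable Hamming
  mismatch budget (default 0), not a heuristic aligner: deterministic,
  dependency-free, and sufficient at the scale of a guide panel. No
  on-/off-target activity scoring is applied; the selection criteria are
  purely locus-based.

## Tiling and pools

`plan_tiling()` splits an ROI of length $L$ into $k = \lceil L / T \rceil$
sub-ROIs for a target length $T$ (default 50,000 bp), then picks actual
cut sites greedily left to right: the first cut is the candidate nearest
the ROI start; each tile's right cut is the candidate nearest its ideal
boundary; the next tile's left cut is the candidate that places the
overlap inside `[overlap_min, overlap_max]` (defaults 2,000–4,000 bp),
as close to `overlap_min` as possible. Ties break toward the smaller
coordinate, making the plan deterministic. Ideal boundaries are
interpolated evenly across the ROI (`start + i·L/k`), with the last
boundary pinned to the ROI end: this guarantees exactly $k$ tiles and
termination at the ROI boundary, whereas stepping `target_length` from
each realised left edge could produce a $k$+1-th sliver tile. The overlap
ceiling of 4,000 bp is deliberately wider than the ~2–3 kbp one would
quote from a text description: published panel coordinates imply overlaps
up to ~3.7 kbp, and the design must accommodate its own motivating
example.

Overlapping tiles cannot be cut in the same reaction: a pool that excises
tile $i$ also cuts at tile $i$+1's boundary, which lies *inside* tile
$i$'s fragment and would shatter it. `assign_pools()` therefore builds a
conflict graph on sub-ROIs (edge ⇔ fragments overlap) and colours it
greedily in index order. Tiling plans are interval graphs in chain form,
for which greedy colouring is optimal: any chain of $k \ge 2$ overlapping
tiles needs exactly two pools, alternating odd/even — pools {1,3,5} and
{2,4} for a five-tile panel. `validate_plan()` re-checks everything
(gaps, overlap bounds, same-pool internal cuts, shared guides) from the
raw intervals, and the test suite re-verifies pool validity with an
independent brute-force check over every pool × fragment × cut site.

## Enrichment QC

* **On-target classification**: a read is on-target iff its alignment
  overlaps the ROI by ≥ 1 bp — no minimum overlap fraction, matching the
  practice of extracting all ROI-overlapping reads for assembly.
  Percentages are reported to two decimals.
* **Coverage**: CIGAR-aware pileup; M/=/X consume reference and
  contribute depth, D/N consume reference without depth. The default
  `mapq_min = 1` excludes multi-mapping "quality zero" reads, a known
  artifact in repeat-rich plant loci; 0 reproduces raw pileups.
* **N50**: largest $\ell$ such that reads ≥ $\ell$ hold at least half
  the summed bases, by descending cumulative sum.
* **Fold enrichment**: mean on-target coverage ÷ mean whole-genome
  coverage. (Published fold-enrichment figures do not always equal the
  ratio of the two printed coverages; the package reports the ratio.)
* **Genotypability**: percentage of bases with depth ≥ `min_depth`
  (default 5), the callable-loci criterion.
* **PASS filter**: reads with mean Q > 7 at FASTQ ingest
  (`read_fastq_stats()`); alignment files are assumed pre-filtered.
  FASTQ I/O is line-based because fixed-buffer FASTQ parsers break on
  ultralong nanopore reads.

## Contig-to-reference comparison

Identity is $100\,(1 - \mathrm{NM}/\mathrm{alignment\ length})$, one
decimal. The NM tag counts non-matching characters (a *distance*); its
complement is what is conventionally reported as percent identity.
`call_variants()` walks the CIGAR and emits one SNV per mismatched
column, one insertion per I run and one deletion per D run, never merging
adjacent runs; indels ≥ 50 bp (the assembly-comparison convention) are
flagged as structural variants. Per-base resolution is required: `=`/`X`
operations, or `M` plus both sequences; MD-tag reconstruction is out of
scope for v1 (dialect complexity, no in-repo test oracle). A variant
overlapping several genes counts once. `find_divergent_regions()` flags
maximal clusters of ≥ `min_events` (default 5) variant events within a
`window` (default 1,000 bp), merging clusters closer than one window —
the desk analogue of eyeballing a dot plot for locally divergent patches.
`dot_segments()` exports alignment segments for external dot-plot
viewers; no rendering is attempted.

## The simulator

`sim_config()` defaults *are* the study conditions the package targets,
chosen once:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 250 kbp | the ROI scale of interest |
| `gc_fraction` | 0.38 | legume-like composition |
| `n_genes` | 30 | gene count of the motivating locus comparison |
| `snv_rate` | 0.005/bp | ≈1,163 SNVs per 234 kbp, the observed divergence |
| `small_indel_rate` | 0.0025/bp | ≈600 indels per 234 kbp |
| `cut_efficiency` | 0.9 | an effective, not perfect, RNP |
| `background_rate` | 0.97 | on-target fractions of a few percent, as observed in Cas9 enrichment without short-fragment depletion |
| `read_length_n50` | 30 kbp | long-read N50 of the motivating run |
| error rates | 2/1/2 % | ≈95% accuracy, R9.4.1-like |

Read lengths are log-normal with $\mu = \log(\mathrm{N50}) - \sigma^2$:
the length-weighted (size-biased) distribution of a log-normal
$(\mu,\sigma)$ is log-normal $(\mu+\sigma^2,\sigma)$, whose median —
the N50, asymptotically — is $e^{\mu+\sigma^2}$. Two parameters, and the
target N50 is verifiable with `read_n50()` itself.

`apply_variants()` plants explicit SVs first, then small indels, then
SNVs, rejection-sampling collisions; the truth table uses VCF-anchored
records so it round-trips through VCF files. `truth_alignment()` converts
the edit list into the exact `=`/`X`/`I`/`D` alignment of haplotype to
reference — the simulator's own ground truth, built without running any
caller, which the variant caller must then reproduce exactly at zero read
error. `digest_and_sequence()` cuts each pool at its guides' sites
independently at `cut_efficiency`, liberates fragments whose two cuts
both succeeded, and samples reads: fragment reads are full-length minus a
small end slack (≤150 bp, library-prep raggedness); background reads are
uniform over the genome with lengths from the same distribution. Errors
are i.i.d. per base — no homopolymer-aware model, though homopolymer
stretches are a known error hotspot of the chemistry this emulates; the
simulator therefore cannot reproduce locally clustered error patterns,
and passing tests say nothing about assembler behaviour in low-complexity
sequence. There is likewise no competitive-sequencing length bias between
short background and long target fragments. The uniform background model
itself is an assumption: no published background model exists for Cas9
enrichment.

Scale choices: interval-only simulation (`with_sequences = FALSE`) lets
the suite check sampling behaviour at 10,000 reads over a 100-Mbp
lengths-only genome without materialising ~300 Mbp of sequence;
sequence-level tests use hundreds of reads over 80–120-kbp references.
Property loops run 30–1,000 instances per invariant, sized so the whole
suite completes in minutes on one CPU.

## Degenerate inputs and numerical choices

* Regions shorter than protospacer+PAM scan to an empty candidate set
  (not an error); planning over them fails with the boundary named.
* `read_n50()` rejects empty or non-positive input; on-target percentage
  of zero reads is reported not-available (`NA`), as is fold enrichment
  over zero genome coverage and gene-overlap percentage of an absent
  variant class.
* kbp truncation uses `floor(bp/100)/10`; all tie-breaks in planning go
  toward the smaller coordinate; greedy colouring follows sub-ROI index
  order.
* PAF records without a `cg:Z` CIGAR are accepted for coverage/on-target
  QC but rejected by variant extraction, which needs per-base detail.
* The ROI and the outermost cut sites are treated as distinct quantities:
  the planner pins cut selection near the ROI boundaries but does not
  force them to coincide, and published panels whose outer guides sit
  just outside the nominal ROI are represented as printed.

## Known limitations

* Off-target counting is exact-match (Hamming) only — no bulges, no
  activity scores.
* One ROI per plan; multi-ROI panels and cost optimisation across flow
  cells are out of scope.
* Variant extraction assumes a single covering alignment; split
  alignments must be compared segment by segment.
* The identity statistic inherits NM's convention of counting indel
  *bases*, so one large SV depresses identity as much as many scattered
  SNVs.
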
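## Enrichment / sequencing QC against a reference: on-target fraction,
## CIGAR-aware per-base coverage, spanning reads, read N50, fold
## enrichment and genotypability.

#' On-target percentage arithmetic
#'
#' `100 * on / total`, rounded to two decimals; `NA` when `total` is zero.
#' Exposed separately so report arithmetic on externally tabulated counts
#' uses the same code path as [classify_on_target()].
#'
#' @param on_count,total_count Read counts.
#' @return Percentage rounded to 2 decimals, or `NA`.
#' @examples
#' on_target_percentage(1794, 54540)  # 3.29
#' @export
on_target_percentage <- function(on_count, total_count) {
  if (total_count == 0) return(NA_real_)
  round(100 * on_count / total_count, 2)
}

#' Classify reads as on- or off-target
#'
#' A read is on-target iff its target interval overlaps the ROI by at
#' least 1 bp (no minimum overlap fraction). Alignments are assumed to be
#' primary mappings (secondary/supplementary records are dropped at load by
#' [read_alignments()]).
#'
#' @param alignments Alignment table.
#' @param roi [genomic_interval()] of the region of interest.
#' @return List with `on_count`, `total_count`, `percentage` (2 decimals;
#'   `NA` when there are no alignments) and the logical vector `on_target`.
#' @export
classify_on_target <- function(alignments, roi) {
  stopifnot(inherits(roi, "genomic_interval"))
  on <- overlap_bp(alignments$contig, alignments$start, alignments$end,
                   roi) > 0
  list(
    on_count = sum(on),
    total_count = nrow(alignments),
    percentage = on_target_percentage(sum(on), nrow(alignments)),
    on_target = on
  )
}

#' Per-base depth profile over an interval
#'
#' CIGAR-aware pileup: an alignment contributes depth at the reference
#' bases covered by its M/=/X operations; deletions (D) and skips (N)
#' consume reference but add no depth. Alignments lacking a CIGAR (e.g.
#' minimal PAF) contribute over their whole target interval. Alignments
#' with `mapq < mapq_min` are ignored — the default of 1 excludes
#' multi-mapping "quality zero" reads, a known artifact source; set 0 to
#' reproduce raw pileups.
#'
#' @param alignments Alignment table.
#' @param interval [genomic_interval()] to profile.
#' @param mapq_min Minimum mapping quality (default 1).
#' @return A `depth_profile`: list with `interval`, integer vector `depth`
#'   of length `interval_length(interval)`, and `mapq_min`.
#' @export
depth_profile <- function(alignments, interval, mapq_min = 1L) {
  stopifnot(inherits(interval, "genomic_interval"))
  L <- interval_length(interval)
  diffv <- numeric(L + 1L)
  keep <- alignments$contig == interval$contig &
    alignments$mapq >= mapq_min &
    alignments$start < interval$end & alignments$end > interval$start
  sub <- alignments[keep, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    cig <- sub$cigar[i]
    if (is.na(cig) || !nzchar(cig) || cig == "*") {
      covs <- IRanges::IRanges(sub$start[i] + 1, sub$end[i])
    } else {
      covs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, pos = sub$start[i] + 1, ops = c("M", "=", "X"),
        reduce.ranges = TRUE)[[1L]]
    }
    ## clip to the interval; IRanges here are 1-based inclusive genome coords
    s <- pmax(IRanges::start(covs) - 1, interval$start)
    e <- pmin(IRanges::end(covs), interval$end)
    ok <- s < e
    s <- s[ok] - interval$start
    e <- e[ok] - interval$start
    for (j in seq_along(s)) {
      diffv[s[j] + 1L] <- diffv[s[j] + 1L] + 1
      diffv[e[j] + 1L] <- diffv[e[j] + 1L] - 1
    }
  }
  structure(list(interval = interval,
                 depth = as.integer(cumsum(diffv[seq_len(L)])),
                 mapq_min = mapq_min),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> ", format_region_string(x$interval),
      "  mean ", round(mean(x$depth), 2), "x  (mapq >= ", x$mapq_min, ")\n",
      sep = "")
  invisible(x)
}

#' Mean per-base coverage of an interval
#'
#' @inheritParams depth_profile
#' @return Mean depth (numeric).
#' @export
mean_depth <- function(alignments, interval, mapq_min = 1L) {
  mean(depth_profile(alignments, interval, mapq_min)$depth)
}

#' Count reads fully spanning a fragment
#'
#' Containment is inclusive at both ends: the alignment's target interval
#' must contain every base of the fragment.
#'
#' @param alignments Alignment table.
#' @param fragment [genomic_interval()] (e.g. a sub-ROI fragment).
#' @return Integer count.
#' @export
count_spanning <- function(alignments, fragment) {
  stopifnot(inherits(fragment, "genomic_interval"))
  sum(alignments$contig == fragment$contig &
      alignments$start <= fragment$start &
      alignments$end >= fragment$end)
}

#' Read-length N50
#'
#' Largest length L such that reads of length >= L together contain at
#' least half of the total bases (computed by descending cumulative sum).
#'
#' @param read_lengths Positive read lengths in bp.
#' @return N50 in bp.
#' @examples
#' read_n50(c(2, 2, 2, 3, 3))  # 3
#' @export
read_n50 <- function(read_lengths) {
  if (length(read_lengths) == 0L) stop("read_n50: empty length list")
  if (any(read_lengths <= 0)) stop("read_n50: lengths must be positive")
  x <- sort(read_lengths, decreasing = TRUE)
  x[which(cumsum(x) >= sum(x) / 2)[1L]]
}

#' Fold enrichment
#'
#' Ratio of mean on-target coverage to mean whole-genome coverage.
#'
#' @param on_target_cov,genome_cov Mean coverages (x-fold).
#' @return Ratio; `NA` when `genome_cov` is zero.
#' @export
fold_enrichment <- function(on_target_cov, genome_cov) {
  if (genome_cov == 0) return(NA_real_)
  on_target_cov / genome_cov
}

#' Genotypability of an interval
#'
#' Percentage of bases callable at a depth threshold: `100 * #{bases with
#' depth >= min_depth} / length`.
#'
#' @param depth A [depth_profile()].
#' @param min_depth Callable-depth threshold (default 5).
#' @return Percentage in `[0, 100]`.
#' @export
genotypability <- function(depth, min_depth = 5L) {
  stopifnot(inherits(depth, "depth_profile"))
  if (length(depth$depth) == 0L) stop("genotypability: zero-length interval")
  100 * sum(depth$depth >= min_depth) / length(depth$depth)
}

#' Full enrichment QC report
#'
#' Computes the sequencing/enrichment summary for a set of aligned reads
#' against a tiling plan: total and on-target counts, on-target
#' percentage, read N50, per-sub-ROI read fraction / mean coverage /
#' spanning counts, ROI and whole-genome mean coverage, fold enrichment
#' and ROI genotypability.
#'
#' @param alignments Alignment table (PASS reads, primary mappings).
#' @param plan A `tiling_plan`.
#' @param genome_lengths Named vector of contig lengths (for whole-genome
#'   coverage); the sum of target-consuming bases is divided by the total.
#' @param mapq_min Mapping-quality threshold for coverage (default 1).
#' @param min_depth Genotypability threshold (default 5).
#' @return A `qc_report` list.
#' @export
qc_report <- function(alignments, plan, genome_lengths, mapq_min = 1L,
                      min_depth = 5L) {
  stopifnot(inherits(plan, "tiling_plan"))
  roi <- plan$roi
  cls <- classify_on_target(alignments, roi)
  on_aln <- alignments[cls$on_target, , drop = FALSE]

  roi_prof <- depth_profile(alignments, roi, mapq_min = mapq_min)

  per_subroi <- lapply(seq_len(nrow(plan$subrois)), function(i) {
    frag <- genomic_interval(plan$subrois$contig[i], plan$subrois$start[i],
                             plan$subrois$end[i])
    ov <- overlap_bp(on_aln$contig, on_aln$start, on_aln$end, frag) > 0
    list(
      index = i,
      read_fraction = if (cls$on_count > 0) sum(ov) / cls$on_count else NA_real_,
      mean_coverage = mean_depth(alignments, frag, mapq_min = mapq_min),
      spanning = count_spanning(alignments, frag)
    )
  })

  ## whole-genome mean coverage: total aligned reference-consuming bases
  ## over total genome length (a full per-base pileup of the genome would
  ## be wasteful for a single mean)
  keep <- alignments$mapq >= mapq_min
  genome_cov <- sum(alignments$end[keep] - alignments$start[keep]) /
    sum(genome_lengths)
  roi_cov <- mean(roi_prof$depth)

  structure(list(
    total_reads = cls$total_count,
    on_target_reads = cls$on_count,
    on_target_pct = cls$percentage,
    read_n50 = if (nrow(alignments)) read_n50(alignments$query_length)
               else NA_real_,
    per_subroi = per_subroi,
    roi_mean_coverage = roi_cov,
    genome_mean_coverage = genome_cov,
    fold_enrichment = fold_enrichment(roi_cov, genome_cov),
    genotypability = genotypability(roi_prof, min_depth = min_depth),
    mapq_min = mapq_min,
    min_depth = min_depth
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  Total aligned PASS reads   ", format(x$total_reads, big.mark = ","), "\n")
  cat("  PASS read N50 (bp)         ", format(x$read_n50, big.mark = ","), "\n")
  cat("  On-target PASS reads on ROI", format(x$on_target_reads, big.mark = ","), "\n")
  cat("  On-target reads %          ", sprintf("%.2f%%", x$on_target_pct), "\n")
  cat("  On-target average coverage ", sprintf("%.2fx", x$roi_mean_coverage), "\n")
  cat("  Whole genome average coverage", sprintf("%.2fx", x$genome_mean_coverage), "\n")
  cat("  Fold enrichment            ", sprintf("%.2fx", x$fold_enrichment), "\n")
  cat("  Genotypability (DP >= ", x$min_depth, ") ",
      sprintf("%.1f%%", x$genotypability), "\n", sep = "")
  invisible(x)
}
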
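## Comparison of a reconstructed contig against a reference region (or a
## second contig): alignment identity from the NM tag, SNV/indel/SV
## extraction from CIGAR alignments, gene-overlap summaries, per-gene read
## density and divergent-region detection.

#' Alignment identity from the NM tag
#'
#' `100 * (1 - nm / alignment_length)`, reported to one decimal. The NM tag
#' counts non-matching characters (mismatches plus inserted and deleted
#' bases); dividing by the alignment length gives a distance, whose
#' complement is the conventional percent identity.
#'
#' @param nm Edit distance (NM tag value).
#' @param alignment_length Alignment length in bp (> 0).
#' @return Percent identity, one decimal.
#' @examples
#' alignment_identity(5, 1000)  # 99.5
#' @export
alignment_identity <- function(nm, alignment_length) {
  if (any(alignment_length <= 0)) {
    stop("alignment_identity: alignment_length must be positive")
  }
  if (any(nm < 0 | nm > alignment_length)) {
    stop("alignment_identity: need 0 <= nm <= alignment_length")
  }
  round(100 * (1 - nm / alignment_length), 1)
}

empty_variant_calls <- function() {
  data.frame(contig = character(0), start = numeric(0), end = numeric(0),
             kind = character(0), size = integer(0),
             query_position = numeric(0), ref = character(0),
             alt = character(0), is_sv = logical(0),
             stringsAsFactors = FALSE)
}

#' Extract variant calls from a contig-to-reference alignment
#'
#' Walks the CIGAR of one alignment and emits one SNV per mismatched
#' aligned column, one insertion per I run and one deletion per D run
#' (adjacent runs are not merged). Coordinates are on the target (0-based
#' half-open); `query_position` is the 0-based offset of the event in the
#' query sequence. Indels of size >= `sv_threshold` are flagged as
#' structural variants.
#'
#' Requires per-base resolution: either `=`/`X` CIGAR operations, or `M`
#' operations together with both sequences so mismatches can be resolved.
#'
#' @param alignment One alignment row (see [read_alignments()]).
#' @param query_seq,target_seq Full query and target sequences (character
#'   or `DNAString`); required when the CIGAR uses `M`, optional for
#'   `=`/`X` CIGARs (alleles are then reported as `N`).
#' @param sv_threshold SV size threshold in bp (default 50, the
#'   assembly-comparison convention).
#' @return Variant table with columns `contig`, `start`, `end`, `kind`,
#'   `size`, `query_position`, `ref`, `alt`, `is_sv`.
#' @export
call_variants <- function(alignment, query_seq = NULL, target_seq = NULL,
                          sv_threshold = 50L) {
  stopifnot(nrow(alignment) == 1L)
  cig <- alignment$cigar
  if (is.na(cig) || !nzchar(cig) || cig == "*") {
    stop("call_variants: alignment has no CIGAR (minimal PAF records are ",
         "accepted for coverage QC only)")
  }
  ops <- cigar_ops(cig)
  if (any(ops$op == "M") && (is.null(query_seq) || is.null(target_seq))) {
    stop("call_variants: CIGAR contains M operations; both query and ",
         "target sequences are required to resolve mismatches ",
         "(or supply an =/X CIGAR)")
  }
  qs <- if (!is.null(query_seq)) strsplit(toupper(as.character(query_seq)),
                                          "")[[1L]] else NULL
  ts <- if (!is.null(target_seq)) strsplit(toupper(as.character(target_seq)),
                                           "")[[1L]] else NULL
  tpos <- alignment$start  # 0-based on target
  qpos <- 0                # 0-based in query
  contig <- alignment$contig
  calls <- list()
  emit <- function(start, end, kind, size, query_position, ref, alt) {
    calls[[length(calls) + 1L]] <<- data.frame(
      contig = contig, start = start, end = end, kind = kind, size = size,
      query_position = query_position, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]
    n <- ops$len[r]
    if (op %in% c("M", "=", "X")) {
      if (op == "X" && is.null(qs)) {
        ## mismatch run, alleles unknown: one SNV per column
        for (j in seq_len(n)) {
          emit(tpos + j - 1, tpos + j, "SNV", 1L, qpos + j - 1,
               "N", "N")
        }
      } else if (op != "=" && !is.null(qs)) {
        qv <- qs[qpos + seq_len(n)]
        tv <- ts[tpos + seq_len(n)]
        mm <- which(qv != tv)
        for (j in mm) {
          emit(tpos + j - 1, tpos + j, "SNV", 1L, qpos + j - 1,
               tv[j], qv[j])
        }
      }
      tpos <- tpos + n
      qpos <- qpos + n
    } else if (op == "I") {
      emit(tpos, tpos, "insertion", n, qpos,
           if (!is.null(ts) && tpos >= 1) ts[tpos] else "N",
           if (!is.null(qs)) paste0(
             if (!is.null(ts) && tpos >= 1) ts[tpos] else "",
             paste(qs[qpos + seq_len(n)], collapse = "")) else "N")
      qpos <- qpos + n
    } else if (op == "D") {
      emit(tpos, tpos + n, "deletion", n, qpos,
           if (!is.null(ts)) paste(ts[tpos + seq_len(n)], collapse = "")
           else "N",
           if (!is.null(ts) && tpos >= 1) ts[tpos] else "N")
      tpos <- tpos + n
    } else if (op == "N") {
      tpos <- tpos + n
    } else if (op == "S") {
      qpos <- qpos + n
    }
    ## H consumes neither
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_variant_calls()
  if (nrow(out)) {
    out$is_sv <- out$kind != "SNV" & out$size >= sv_threshold
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Flag variants overlapping gene features
#'
#' A variant overlaps a gene iff their intervals share at least 1 bp; a
#' variant overlapping several genes counts once (boolean per variant).
#'
#' @param variants Variant table (`contig`, `start`, `end`).
#' @param genes Gene table; only `gene` features are considered.
#' @return The variant table with a logical `overlaps_gene` column.
#' @export
annotate_gene_overlap <- function(variants, genes) {
  g <- genes[genes$feature_kind == "gene", , drop = FALSE]
  variants$overlaps_gene <- vapply(seq_len(nrow(variants)), function(i) {
    any(g$contig == variants$contig[i] &
        g$start < variants$end[i] &
        g$end > variants$start[i])
  }, logical(1L))
  variants
}

#' Per-kind gene-overlap summary
#'
#' For each variant kind (SNV, insertion, deletion): the total count, the
#' count overlapping annotated genes, and the percentage to one decimal
#' (`NA` when no variant of that kind exists).
#'
#' @param variants Variant table.
#' @param genes Gene table (may have zero rows).
#' @return `data.frame` with columns `kind`, `n`, `n_overlapping`,
#'   `percentage`.
#' @export
summarize_gene_overlap <- function(variants, genes) {
  variants <- annotate_gene_overlap(variants, genes)
  kinds <- c("SNV", "insertion", "deletion")
  out <- lapply(kinds, function(k) {
    v <- variants[variants$kind == k, , drop = FALSE]
    data.frame(kind = k, n = nrow(v), n_overlapping = sum(v$overlaps_gene),
               percentage = gene_overlap_percentage(sum(v$overlaps_gene),
                                                    nrow(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-overlap percentage arithmetic
#'
#' `100 * overlapping / count`, one decimal; `NA` for an empty kind.
#'
#' @param n_overlapping,n Counts.
#' @return Percentage, one decimal.
#' @examples
#' gene_overlap_percentage(427, 1163)  # 36.7
#' @export
gene_overlap_percentage <- function(n_overlapping, n) {
  if (n == 0) return(NA_real_)
  round(100 * n_overlapping / n, 1)
}

#' Read density over a gene
#'
#' Number of alignments overlapping the gene interval by at least 1 bp,
#' normalised by gene length: reads per kbp.
#'
#' @param alignments Alignment table.
#' @param gene One gene row (`contig`, `start`, `end`) or a
#'   [genomic_interval()].
#' @return Reads per kbp.
#' @export
gene_read_density <- function(alignments, gene) {
  if (inherits(gene, "genomic_interval")) {
    gi <- gene
  } else {
    stopifnot(nrow(gene) == 1L)
    gi <- genomic_interval(gene$contig, gene$start, gene$end)
  }
  n <- sum(overlap_bp(alignments$contig, alignments$start, alignments$end,
                      gi) > 0)
  n * 1000 / interval_length(gi)
}

#' Detect divergent regions from variant clustering
#'
#' Finds maximal regions where at least `min_events` variant events fall
#' within any `window`-bp span; dense spans closer than `window` bp to each
#' other are merged. Returns the merged regions in coordinate order, each
#' extended to cover its member events.
#'
#' @param variants Variant table (sorted or not; positions taken from
#'   `start`).
#' @param window Clustering window in bp (default 1,000).
#' @param min_events Minimum events within a window (default 5).
#' @return `data.frame` of regions (`contig`, `start`, `end`, `n_events`).
#' @export
find_divergent_regions <- function(variants, window = 1000L,
                                   min_events = 5L) {
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), n_events = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(variants) < min_events) return(empty)
  out <- list()
  for (ct in unique(variants$contig)) {
    pos <- sort(variants$start[variants$contig == ct])
    m <- length(pos)
    if (m < min_events) next
    ## seed spans: windows of min_events consecutive events within `window` bp
    i_seed <- which(pos[seq_len(m - min_events + 1L) + min_events - 1L] -
                      pos[seq_len(m - min_events + 1L)] < window)
    if (!length(i_seed)) next
    spans <- data.frame(start = pos[i_seed],
                        end = pos[i_seed + min_events - 1L] + 1)
    ## merge spans separated by less than `window`
    merged <- spans[1L, , drop = FALSE]
    for (r in seq_len(nrow(spans))[-1L]) {
      last <- nrow(merged)
      if (spans$start[r] - merged$end[last] < window) {
        merged$end[last] <- max(merged$end[last], spans$end[r])
      } else {
        merged <- rbind(merged, spans[r, ])
      }
    }
    merged$contig <- ct
    merged$n_events <- vapply(seq_len(nrow(merged)), function(r) {
      sum(pos >= merged$start[r] & pos < merged$end[r])
    }, integer(1L))
    out[[ct]] <- merged[, c("contig", "start", "end", "n_events")]
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export alignment segments for dot-plot visualisation
#'
#' One row per alignment: target start/end, query start/end and strand, the
#' segment layout consumed by external dot-plot viewers.
#'
#' @param alignments Alignment table.
#' @return `data.frame` with columns `target`, `target_start`,
#'   `target_end`, `query`, `query_start`, `query_end`, `strand`.
#' @export
dot_segments <- function(alignments) {
  qspan <- ifelse(is.na(alignments$cigar), alignments$query_length,
                  cigar_query_span(ifelse(is.na(alignments$cigar), "1M",
                                          alignments$cigar)))
  data.frame(
    target = alignments$contig,
    target_start = alignments$start,
    target_end = alignments$end,
    query = alignments$qname,
    query_start = 0,
    query_end = qspan,
    strand = alignments$strand,
    stringsAsFactors = FALSE
  )
}

#' Compare a reconstructed contig against a reference region
#'
#' Bundles the comparison operations into one report: identity from the NM
#' tag, variant calls with SV flags, per-kind gene-overlap summary and
#' divergent-region detection.
#'
#' @param alignment One contig-to-reference alignment row (CIGAR and NM
#'   required).
#' @param query_seq,target_seq Sequences (required for `M` CIGARs).
#' @param genes Gene table (may be empty).
#' @param sv_threshold SV size threshold (default 50 bp).
#' @param window,min_events Divergent-region parameters.
#' @return A `comparison_report` list with elements `identity_pct`,
#'   `variants`, `gene_overlap`, `divergent_regions`, `n_snv`, `n_ins`,
#'   `n_del`.
#' @export
compare_contig <- function(alignment, query_seq = NULL, target_seq = NULL,
                           genes = NULL, sv_threshold = 50L,
                           window = 1000L, min_events = 5L) {
  alen <- alignment$end - alignment$start
  variants <- call_variants(alignment, query_seq, target_seq,
                            sv_threshold = sv_threshold)
  if (is.null(genes)) {
    genes <- data.frame(contig = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        gene_id = character(0), feature_kind = character(0),
                        stringsAsFactors = FALSE)
  }
  variants <- annotate_gene_overlap(variants, genes)
  structure(list(
    identity_pct = alignment_identity(alignment$nm, alen),
    variants = variants,
    n_snv = sum(variants$kind == "SNV"),
    n_ins = sum(variants$kind == "insertion"),
    n_del = sum(variants$kind == "deletion"),
    gene_overlap = summarize_gene_overlap(variants, genes),
    divergent_regions = find_divergent_regions(variants, window = window,
                                               min_events = min_events)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> identity ", sprintf("%.1f%%", x$identity_pct),
      "; ", x$n_snv, " SNVs, ", x$n_ins, " insertions, ", x$n_del,
      " deletions (", sum(x$variants$is_sv), " SV)\n", sep = "")
  print(x$gene_overlap, row.names = FALSE)
  if (nrow(x$divergent_regions)) {
    cat("divergent regions:\n")
    print(x$divergent_regions, row.names = FALSE)
  }
  invisible(x)
}
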
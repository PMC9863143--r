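## CIGAR arithmetic, thin wrappers over GenomicAlignments.

#' CIGAR span helpers
#'
#' `cigar_ref_span()` returns the number of reference (target) bases consumed
#' by a CIGAR string (operations M/=/X/D/N); `cigar_query_span()` the number
#' of query bases consumed (M/=/X/I/S). Vectorised over `cigar`.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of spans in bp.
#' @examples
#' cigar_ref_span("10M2D5M")   # 17
#' cigar_query_span("10M2D5M") # 15
#' @export
cigar_ref_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' @rdname cigar_ref_span
#' @export
cigar_query_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar, after.soft.clipping = FALSE)
}

## Explode a single CIGAR into a data.frame of (op, len).
cigar_ops <- function(cigar) {
  stopifnot(length(cigar) == 1L, !is.na(cigar), nzchar(cigar))
  data.frame(
    op = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
    len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]],
    stringsAsFactors = FALSE
  )
}

## Assert the CIGAR consumption invariants on an alignment table
## (ref span == end - start; query span == query_length when known).
check_alignment_invariants <- function(aln) {
  if (nrow(aln) == 0L) return(invisible(aln))
  has_cigar <- !is.na(aln$cigar) & nzchar(aln$cigar)
  if (any(has_cigar)) {
    rs <- cigar_ref_span(aln$cigar[has_cigar])
    bad <- which(rs != (aln$end[has_cigar] - aln$start[has_cigar]))
    if (length(bad)) {
      stop("CIGAR reference span disagrees with target interval for record(s): ",
           paste(head(aln$qname[has_cigar][bad], 5L), collapse = ", "))
    }
    ql <- aln$query_length[has_cigar]
    known <- !is.na(ql)
    if (any(known)) {
      qs <- cigar_query_span(aln$cigar[has_cigar][known])
      bad <- which(qs != ql[known])
      if (length(bad)) {
        stop("CIGAR query span disagrees with query length for record(s): ",
             paste(head(aln$qname[has_cigar][known][bad], 5L), collapse = ", "))
      }
    }
  }
  invisible(aln)
}
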
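#' Genomic intervals
#'
#' `genomic_interval()` constructs the package's universal location type: a
#' single contig-anchored interval stored 0-based half-open. All public
#' string/report I/O uses the 1-based inclusive dialect (see
#' [parse_region_string()] / [format_region_string()]).
#'
#' @param contig Contig (chromosome) identifier.
#' @param start 0-based start (inclusive).
#' @param end 0-based end (exclusive); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr1", 0, 100)
#' interval_length(gi)
#' @export
genomic_interval <- function(contig, start, end, strand = "*") {
  stopifnot(length(contig) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", "*")) {
    stop("strand must be one of '+', '-', '*'")
  }
  structure(
    list(contig = as.character(contig), start = start, end = end,
         strand = strand),
    class = "genomic_interval"
  )
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format_region_string(x),
      if (x$strand != "*") paste0(" (", x$strand, ")") else "",
      "  [", format(interval_length(x), big.mark = ","), " bp]\n", sep = "")
  invisible(x)
}

#' Parse a human-readable locus string
#'
#' Accepts the `"contig:start-end"` dialect used in genome browsers and
#' publication tables, e.g. `"Chr05:38,489,481-38,723,757"`. Coordinates are
#' interpreted as 1-based inclusive and converted to the internal 0-based
#' half-open representation. Thousands separators (commas) are permitted.
#'
#' @param text Region string.
#' @return A [genomic_interval()].
#' @examples
#' roi <- parse_region_string("Chr05:38,489,481-38,723,757")
#' interval_length(roi)  # 234277
#' @export
parse_region_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", text))[[1L]]
  if (length(m) != 4L) {
    stop("malformed region string: '", text,
         "' (expected '<contig>:<start>-<end>')")
  }
  start1 <- suppressWarnings(as.numeric(gsub(",", "", m[3L], fixed = TRUE)))
  end1 <- suppressWarnings(as.numeric(gsub(",", "", m[4L], fixed = TRUE)))
  if (is.na(start1) || is.na(end1)) {
    stop("malformed coordinate in region string: '", text, "'")
  }
  if (start1 < 1) stop("coordinates are 1-based; got start ", start1)
  if (start1 > end1) {
    stop("region start (", start1, ") exceeds end (", end1, ") in '", text, "'")
  }
  genomic_interval(m[2L], start1 - 1, end1)
}

#' Format an interval as a canonical region string
#'
#' Inverse of [parse_region_string()]: emits 1-based inclusive coordinates
#' with comma thousands separators.
#'
#' @param x A `genomic_interval`.
#' @return Character scalar such as `"Chr05:38,489,481-38,723,757"`.
#' @export
format_region_string <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  paste0(x$contig, ":",
         format(x$start + 1, big.mark = ",", scientific = FALSE, trim = TRUE),
         "-",
         format(x$end, big.mark = ",", scientific = FALSE, trim = TRUE))
}

#' Overlap length between two intervals
#'
#' Total function: intervals on different contigs overlap by 0 bp.
#'
#' @param a,b `genomic_interval` objects.
#' @return Overlap length in bp (0 when disjoint or on different contigs).
#' @export
interval_overlap <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$contig != b$contig) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

## Vectorised overlap between a single interval and table columns
## (0-based half-open on both sides); used by gene/variant bookkeeping.
overlap_bp <- function(contig, start, end, iv) {
  same <- contig == iv$contig
  o <- pmax(0, pmin(end, iv$end) - pmax(start, iv$start))
  o[!same] <- 0
  o
}
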
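## SpCas9 guide candidate enumeration and filtering.
##
## Conventions: a candidate is a 20-nt protospacer plus an adjacent PAM
## (default NGG). The protospacer interval is stored 0-based half-open on
## the plus strand of the genome; for minus-strand candidates the PAM lies
## immediately 5' of the interval in genome coordinates and the stored
## protospacer sequence is the 5'->3' spacer as synthesised. The blunt cut
## falls 3 bp 5' of the PAM, i.e. between protospacer positions 17 and 18;
## `cut_position` is the 0-based genome position of the last base left of
## the cut.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Positions i (1-based, i <= L - len(pattern) + 1) where the IUPAC pattern
## matches chars (a character vector of A/C/G/T/N). A subject N matches
## nothing, including pattern N.
iupac_match_positions <- function(chars, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1L]]
  if (any(!pat %in% names(IUPAC_SETS))) {
    stop("PAM pattern contains non-IUPAC symbol(s): ",
         paste(setdiff(pat, names(IUPAC_SETS)), collapse = ", "))
  }
  L <- length(chars)
  k <- length(pat)
  if (L < k) return(integer(0))
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    ok <- ok & chars[seq.int(j, j + n_win - 1L)] %in% IUPAC_SETS[[pat[j]]]
  }
  which(ok)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

empty_candidates <- function() {
  data.frame(id = character(0), protospacer = character(0),
             pam = character(0), contig = character(0), start = numeric(0),
             end = numeric(0), strand = character(0),
             cut_position = numeric(0), stringsAsFactors = FALSE)
}

#' Enumerate protospacer candidates in a region
#'
#' Scans both strands of `region` for every 20-nt window whose adjacent
#' 3'-side trinucleotide matches `pam_pattern` (IUPAC; default `NGG` for
#' SpCas9). Windows containing N in the protospacer or PAM are excluded.
#' Candidates are returned sorted by cut position.
#'
#' @param genome Reference as returned by [read_reference()].
#' @param region A [genomic_interval()] within the genome.
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param spacer_length Protospacer length, default 20.
#' @return Candidate table with columns `id`, `protospacer`, `pam`,
#'   `contig`, `start`, `end` (0-based half-open protospacer interval),
#'   `strand`, `cut_position`.
#' @export
scan_protospacers <- function(genome, region, pam_pattern = "NGG",
                              spacer_length = 20L) {
  stopifnot(inherits(region, "genomic_interval"))
  if (!region$contig %in% names(genome)) {
    stop("region contig '", region$contig, "' not present in the reference")
  }
  clen <- contig_lengths(genome)[[region$contig]]
  if (region$end > clen) {
    stop("region end ", region$end, " exceeds contig length ", clen)
  }
  sl <- as.integer(spacer_length)
  plen <- nchar(pam_pattern)
  if (interval_length(region) < sl + plen) return(empty_candidates())

  seq <- as.character(Biostrings::subseq(genome[[region$contig]],
                                         region$start + 1, region$end))
  chars <- strsplit(seq, "")[[1L]]
  is_n <- chars == "N"
  ## cumulative N count lets us test any window for N in O(1)
  ncum <- c(0L, cumsum(is_n))
  window_has_n <- function(from, to) (ncum[to + 1L] - ncum[from]) > 0L

  out <- list()
  ## plus strand: [protospacer sl nt][PAM] ; PAM match at position p means
  ## protospacer occupies region positions [p - sl, p - 1]
  pam_hits <- iupac_match_positions(chars, pam_pattern)
  pam_hits <- pam_hits[pam_hits > sl]
  if (length(pam_hits)) {
    keep <- !vapply(pam_hits, function(p) window_has_n(p - sl, p - 1L),
                    logical(1L))
    pam_hits <- pam_hits[keep]
  }
  if (length(pam_hits)) {
    start0 <- region$start + pam_hits - sl - 1L
    out$plus <- data.frame(
      protospacer = substring(seq, pam_hits - sl, pam_hits - 1L),
      pam = substring(seq, pam_hits, pam_hits + plen - 1L),
      contig = region$contig,
      start = start0,
      end = start0 + sl,
      strand = "+",
      cut_position = start0 + sl - 4L,
      stringsAsFactors = FALSE
    )
  }
  ## minus strand: in plus-strand coordinates the layout is
  ## [revcomp(PAM)][revcomp(protospacer)] ; match revcomp(pattern) at q,
  ## protospacer occupies region positions [q + plen, q + plen + sl - 1]
  rc_pat <- revcomp(pam_pattern)
  rc_hits <- iupac_match_positions(chars, rc_pat)
  rc_hits <- rc_hits[rc_hits + plen + sl - 1L <= length(chars)]
  if (length(rc_hits)) {
    keep <- !vapply(rc_hits, function(q)
      window_has_n(q + plen, q + plen + sl - 1L), logical(1L))
    rc_hits <- rc_hits[keep]
  }
  if (length(rc_hits)) {
    start0 <- region$start + rc_hits + plen - 1L
    proto_fwd <- substring(seq, rc_hits + plen, rc_hits + plen + sl - 1L)
    pam_fwd <- substring(seq, rc_hits, rc_hits + plen - 1L)
    out$minus <- data.frame(
      protospacer = vapply(proto_fwd, revcomp, character(1L),
                           USE.NAMES = FALSE),
      pam = vapply(pam_fwd, revcomp, character(1L), USE.NAMES = FALSE),
      contig = region$contig,
      start = start0,
      end = start0 + sl,
      strand = "-",
      cut_position = start0 + 2L,
      stringsAsFactors = FALSE
    )
  }
  cands <- do.call(rbind, out)
  if (is.null(cands) || nrow(cands) == 0L) return(empty_candidates())
  cands <- cands[order(cands$cut_position, cands$start, cands$strand), ,
                 drop = FALSE]
  cands <- cbind(id = sprintf("cand%05d", seq_len(nrow(cands))), cands,
                 stringsAsFactors = FALSE)
  rownames(cands) <- NULL
  cands
}

#' Blunt cut site of a guide candidate
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, between protospacer positions 17
#' and 18 (5'->3'). Returns the 0-based genome position of the last base on
#' the left of the cut (the cut falls between this position and the next).
#'
#' @param candidates Candidate table (one or more rows) with columns
#'   `start`, `end`, `strand`.
#' @return Numeric vector of 0-based cut positions.
#' @export
cut_site <- function(candidates) {
  stopifnot(all(c("start", "end", "strand") %in% names(candidates)))
  ifelse(candidates$strand == "+", candidates$end - 4, candidates$start + 2)
}

## 23-bp protospacer+PAM footprint, 0-based half-open
candidate_footprint <- function(candidates, pam_length = 3L) {
  data.frame(
    contig = candidates$contig,
    start = ifelse(candidates$strand == "+", candidates$start,
                   candidates$start - pam_length),
    end = ifelse(candidates$strand == "+", candidates$end + pam_length,
                 candidates$end)
  )
}

#' Count genome-wide matches of a guide
#'
#' Exhaustive scan of every contig on both strands for sites where the
#' protospacer matches with at most `max_mismatches` Hamming mismatches
#' *and* the adjacent PAM matches `pam_pattern`. The candidate's own site is
#' always counted, so the result is at least 1; a guide is considered
#' unique when the count equals 1.
#'
#' @param protospacer 20-nt spacer sequence (5'->3').
#' @param genome Reference as returned by [read_reference()].
#' @param max_mismatches Hamming mismatch budget over the protospacer
#'   (default 0, i.e. an exact single-occurrence test).
#' @param pam_pattern IUPAC PAM, default `"NGG"`.
#' @return Integer occurrence count.
#' @export
count_genomic_matches <- function(protospacer, genome, max_mismatches = 0L,
                                  pam_pattern = "NGG") {
  proto <- Biostrings::DNAString(toupper(protospacer))
  sl <- length(proto)
  plen <- nchar(pam_pattern)
  pam_ok <- function(pam_seq) {
    ch <- strsplit(as.character(pam_seq), "")[[1L]]
    length(iupac_match_positions(ch, pam_pattern)) == 1L
  }
  total <- 0L
  for (ct in names(genome)) {
    subject <- genome[[ct]]
    L <- length(subject)
    ## plus strand: protospacer then PAM on its 3' side
    hits <- Biostrings::matchPattern(proto, subject,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    for (i in seq_along(hits)) {
      e <- Biostrings::end(hits)[i]
      if (e + plen <= L &&
          pam_ok(Biostrings::subseq(subject, e + 1L, e + plen))) {
        total <- total + 1L
      }
    }
    ## minus strand: search the reverse complement of the spacer; the PAM
    ## sits immediately 5' of the hit in plus-strand coordinates
    hits <- Biostrings::matchPattern(Biostrings::reverseComplement(proto),
                                     subject,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    for (i in seq_along(hits)) {
      s <- Biostrings::start(hits)[i]
      if (s - plen >= 1L &&
          pam_ok(Biostrings::reverseComplement(
            Biostrings::subseq(subject, s - plen, s - 1L)))) {
        total <- total + 1L
      }
    }
  }
  total
}

#' Filter guide candidates by locus criteria
#'
#' Annotates each candidate with four boolean flags and an overall `pass`:
#' * `in_gene` — the 23-bp protospacer+PAM footprint lies entirely within a
#'   `gene` or `CDS` feature;
#' * `covered` — every footprint base has short-read depth >=
#'   `min_depth`; footprint bases missing from the depth profile fail this
#'   flag with a warning;
#' * `variant_free` — no known variant overlaps the footprint;
#' * `unique` — [count_genomic_matches()] equals 1.
#' Non-passing candidates are retained (flags populated) for reporting.
#'
#' @param candidates Candidate table from [scan_protospacers()].
#' @param genes Gene table (see [read_genes()]).
#' @param variants Variant table (see [read_variants()]); may be empty.
#' @param depth A [depth_profile()] covering the scanned region, or `NULL`
#'   to skip the coverage criterion (flag set to `NA`).
#' @param genome Reference genome for the uniqueness scan, or `NULL` to
#'   skip (flag `NA`).
#' @param min_depth Minimum acceptable depth, default 5.
#' @param max_mismatches Mismatch budget for the uniqueness scan, default 0.
#' @return The candidate table with added logical columns `in_gene`,
#'   `covered`, `variant_free`, `unique`, `pass`.
#' @export
filter_candidates <- function(candidates, genes, variants, depth = NULL,
                              genome = NULL, min_depth = 5L,
                              max_mismatches = 0L) {
  n <- nrow(candidates)
  fp <- candidate_footprint(candidates)

  gene_feats <- genes[genes$feature_kind %in% c("gene", "CDS"), , drop = FALSE]
  in_gene <- vapply(seq_len(n), function(i) {
    any(gene_feats$contig == fp$contig[i] &
        gene_feats$start <= fp$start[i] &
        gene_feats$end >= fp$end[i])
  }, logical(1L))

  if (is.null(variants) || nrow(variants) == 0L) {
    variant_free <- rep(TRUE, n)
  } else {
    variant_free <- vapply(seq_len(n), function(i) {
      !any(variants$contig == fp$contig[i] &
           variants$start < fp$end[i] &
           variants$end > fp$start[i])
    }, logical(1L))
  }

  if (is.null(depth)) {
    covered <- rep(NA, n)
  } else {
    stopifnot(inherits(depth, "depth_profile"))
    iv <- depth$interval
    covered <- vapply(seq_len(n), function(i) {
      if (fp$contig[i] != iv$contig ||
          fp$start[i] < iv$start || fp$end[i] > iv$end) {
        warning("candidate ", candidates$id[i],
                " footprint extends beyond the depth profile; ",
                "failing the coverage criterion", call. = FALSE)
        return(FALSE)
      }
      idx <- seq.int(fp$start[i] - iv$start + 1L, fp$end[i] - iv$start)
      d <- depth$depth[idx]
      if (anyNA(d)) {
        warning("candidate ", candidates$id[i],
                " has missing depth values; failing the coverage criterion",
                call. = FALSE)
        return(FALSE)
      }
      all(d >= min_depth)
    }, logical(1L))
  }

  if (is.null(genome)) {
    unique_flag <- rep(NA, n)
  } else {
    unique_flag <- vapply(seq_len(n), function(i) {
      count_genomic_matches(candidates$protospacer[i], genome,
                            max_mismatches = max_mismatches) == 1L
    }, logical(1L))
  }

  candidates$in_gene <- in_gene
  candidates$covered <- covered
  candidates$variant_free <- variant_free
  candidates$unique <- unique_flag
  candidates$pass <- in_gene & variant_free &
    (!is.na(covered) & covered) & (!is.na(unique_flag) & unique_flag)
  candidates
}
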
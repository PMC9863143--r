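## Readers and writers for the standard formats the pipeline consumes.
## Internal convention everywhere: 0-based half-open coordinates. The
## conversions happen here, at the format boundary, and nowhere else.

#' Load and validate a reference genome
#'
#' Reads a FASTA file (or accepts a named character vector / `DNAStringSet`),
#' uppercases the sequence and validates that contig names are unique and the
#' alphabet is restricted to A/C/G/T/N. Ambiguity codes other than N are
#' rejected: guide scanning has no defined behaviour over them, and N itself
#' is never matched by PAM or protospacer scans.
#'
#' @param x Path to a FASTA file, a named character vector, or a
#'   `Biostrings::DNAStringSet`.
#' @return A `DNAStringSet` with unique names (class also
#'   `reference_genome` semantics: use [contig_lengths()] for lengths).
#' @export
read_reference <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    seqs <- Biostrings::DNAStringSet(x)
  } else if (methods::is(x, "DNAStringSet")) {
    seqs <- x
  } else {
    stop("cannot interpret reference input of class ", class(x)[1L])
  }
  ## FASTA headers: contig name is the first whitespace-delimited word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig names in reference: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  extra <- freq[!names(freq) %in% c("A", "C", "G", "T", "N")]
  if (sum(extra) > 0) {
    stop("reference contains ambiguity codes other than N: ",
         paste(names(extra)[extra > 0], collapse = ", "))
  }
  seqs
}

#' @rdname read_reference
#' @param genome A reference as returned by [read_reference()].
#' @export
contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Read gene features from GFF3 or BED
#'
#' GFF3 input is 1-based inclusive, BED 0-based half-open; both are
#' normalised to the internal 0-based half-open convention. For GFF3, the
#' feature kind is taken from the `type` column (gene/CDS/exon/intron kept,
#' other types dropped); for BED every record is a `gene`.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `gene_id`, `feature_kind`.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "CDS", "exon", "intron")
    gr <- gr[keep]
    id <- gr$ID
    if (is.null(id)) id <- rep(NA_character_, length(gr))
    if (!is.null(gr$Parent)) {
      parent <- vapply(gr$Parent, function(p)
        if (length(p)) as.character(p)[1L] else NA_character_, character(1L))
      id <- ifelse(is.na(id) | as.character(gr$type) != "gene",
                   ifelse(is.na(parent), id, parent), id)
    }
    data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = as.character(id),
      feature_kind = as.character(gr$type),
      stringsAsFactors = FALSE
    )
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("feature", seq_along(gr)),
      feature_kind = "gene",
      stringsAsFactors = FALSE
    )
  } else {
    stop("unknown gene annotation format: '.", ext, "' (expected GFF3 or BED)")
  }
}

#' Write gene features as GFF3
#'
#' @param genes Gene table as returned by [read_genes()].
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(genes$start + 1, genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  gr$type <- genes$feature_kind
  gr$ID <- genes$gene_id
  gr$source <- "castile"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Uses `VariantAnnotation::readVcf()` and flattens records to a table,
#' expanding multi-allelic sites to one row per ALT allele. The variant
#' interval spans the REF allele (`[pos, pos + nchar(ref))`, 0-based).
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return `data.frame` with columns `contig`, `start`, `end`, `ref`, `alt`,
#'   `kind` (`SNV`/`insertion`/`deletion`/`other`).
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  idx <- rep(seq_along(rr), n_alt)
  alt <- as.character(unlist(altl))
  pos0 <- GenomicRanges::start(rr)[idx] - 1
  ref_e <- ref[idx]
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr))[idx],
    start = pos0,
    end = pos0 + nchar(ref_e),
    ref = ref_e,
    alt = alt,
    stringsAsFactors = FALSE
  )
  out$kind <- classify_variant(out$ref, out$alt)
  out
}

classify_variant <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    ifelse(nchar(alt) > nchar(ref), "insertion",
      ifelse(nchar(ref) > nchar(alt), "deletion", "other")))
}

#' Write a variant table as minimal VCF v4.2
#'
#' Emits the eight mandatory columns (QUAL/FILTER as `.`/`PASS`, INFO
#' carrying the size class). Coordinates convert back to 1-based.
#'
#' @param variants Variant table (columns `contig`, `start`, `ref`, `alt`).
#' @param path Output path.
#' @param source_tag Value for the `##source` header line.
#' @export
write_variants_vcf <- function(variants, path, source_tag = "castile") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Variant kind\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(variants)) {
    v <- variants[order(variants$contig, variants$start), , drop = FALSE]
    kind <- if ("kind" %in% names(v)) v$kind else classify_variant(v$ref, v$alt)
    body <- paste(v$contig, v$start + 1, ".", v$ref, v$alt, ".", "PASS",
                  paste0("KIND=", kind), sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM, BAM or PAF
#'
#' SAM/BAM records are read through `Rsamtools` (text SAM is converted to a
#' temporary BAM first); unmapped, secondary and supplementary records are
#' dropped with a logged count. PAF is parsed directly; records lacking a
#' `cg:Z` CIGAR tag keep `cigar = NA` and are usable for coverage/on-target
#' QC but rejected by variant extraction. All target coordinates are 0-based
#' half-open. CIGAR consumption invariants are asserted on load.
#'
#' @param path Path to a `.sam`, `.bam` or `.paf` file.
#' @return `data.frame` with columns `qname`, `query_length`, `contig`,
#'   `start`, `end`, `strand`, `cigar`, `mapq`, `nm`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    read_alignments_bam(path, is_sam = ext == "sam")
  } else if (ext == "paf") {
    read_alignments_paf(path)
  } else {
    stop("unknown alignment format: '.", ext, "' (expected SAM, BAM or PAF)")
  }
}

read_alignments_bam <- function(path, is_sam = FALSE) {
  if (is_sam) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "qwidth"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n_all <- length(res$qname)
  mapped <- !is.na(res$pos)
  n_drop <- n_all - sum(mapped)
  if (n_drop > 0) {
    message("read_alignments: dropped ", n_drop, " unmapped record(s)")
  }
  cig <- as.character(res$cigar)[mapped]
  start0 <- res$pos[mapped] - 1
  aln <- data.frame(
    qname = res$qname[mapped],
    query_length = res$qwidth[mapped],
    contig = as.character(res$rname)[mapped],
    start = start0,
    end = start0 + cigar_ref_span(cig),
    strand = as.character(res$strand)[mapped],
    cigar = cig,
    mapq = res$mapq[mapped],
    nm = if (!is.null(res$tag$NM)) res$tag$NM[mapped] else NA_integer_,
    stringsAsFactors = FALSE
  )
  check_alignment_invariants(aln)
  aln
}

read_alignments_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(qname = character(0), query_length = integer(0),
                      contig = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      cigar = character(0), mapq = integer(0),
                      nm = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    stop("PAF line ", bad[1L], " has fewer than 12 columns")
  }
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  tag_value <- function(fl, prefix) {
    hit <- fl[startsWith(fl, prefix)]
    if (length(hit)) sub(prefix, "", hit[1L], fixed = TRUE) else NA_character_
  }
  tags_cg <- vapply(fields, tag_value, character(1L), prefix = "cg:Z:")
  tags_nm <- vapply(fields, tag_value, character(1L), prefix = "NM:i:")
  matches <- as.numeric(get(10L))
  blocklen <- as.numeric(get(11L))
  aln <- data.frame(
    qname = get(1L),
    query_length = as.integer(get(2L)),
    contig = get(6L),
    start = as.numeric(get(8L)),
    end = as.numeric(get(9L)),
    strand = get(5L),
    cigar = tags_cg,
    mapq = as.integer(get(12L)),
    nm = ifelse(is.na(tags_nm), as.integer(blocklen - matches),
                as.integer(tags_nm)),
    stringsAsFactors = FALSE
  )
  ## PAF query_length counts the full query; CIGARs in cg:Z omit clips, so
  ## only the reference-span invariant is checkable here.
  has_cigar <- !is.na(aln$cigar)
  if (any(has_cigar)) {
    rs <- cigar_ref_span(aln$cigar[has_cigar])
    bad <- which(rs != (aln$end[has_cigar] - aln$start[has_cigar]))
    if (length(bad)) {
      stop("PAF cg:Z CIGAR disagrees with target span for record(s): ",
           paste(head(aln$qname[has_cigar][bad], 5L), collapse = ", "))
    }
  }
  aln
}

#' Write a minimal SAM file
#'
#' Used by the simulator for truth alignments and by tests to build text
#' fixtures. One record per alignment row; sequence/quality columns are `*`
#' unless sequences are supplied.
#'
#' @param aln Alignment table (see [read_alignments()] for columns).
#' @param path Output path (`.sam`).
#' @param ref_lengths Named vector of contig lengths for the `@SQ` header.
#' @param seqs Optional named character vector of read sequences.
#' @export
write_sam <- function(aln, path, ref_lengths, seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:",
                  format(ref_lengths, scientific = FALSE, trim = TRUE)))
  if (nrow(aln)) {
    seq_col <- rep("*", nrow(aln))
    if (!is.null(seqs)) {
      hit <- match(aln$qname, names(seqs))
      seq_col <- ifelse(is.na(hit), "*", unname(seqs[hit]))
    }
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    nm_tag <- ifelse(is.na(aln$nm), "", paste0("\tNM:i:", aln$nm))
    body <- paste0(aln$qname, "\t", flag, "\t", aln$contig, "\t",
                   format(aln$start + 1, scientific = FALSE, trim = TRUE),
                   "\t", aln$mapq, "\t", aln$cigar, "\t*\t0\t0\t",
                   seq_col, "\t*", nm_tag)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a FASTQ file with a PASS quality filter
#'
#' Computes each read's mean Phred quality and flags reads with mean
#' Q > `q_pass` as PASS, mirroring the conventional long-read quality gate.
#' FASTQ records are handled line-based (4 lines per record), which is safe
#' for ultralong reads.
#'
#' @param path FASTQ path.
#' @param q_pass PASS threshold on mean quality (default 7).
#' @return `data.frame` with columns `name`, `length`, `mean_q`, `pass`.
#' @export
read_fastq_stats <- function(path, q_pass = 7) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4")
  }
  idx <- seq(1L, length(lines), by = 4L)
  name <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  if (any(nchar(seqs) != nchar(quals))) {
    stop("malformed FASTQ: sequence/quality length mismatch for record(s): ",
         paste(head(name[nchar(seqs) != nchar(quals)], 5L), collapse = ", "))
  }
  mean_q <- vapply(quals, function(q) mean(utf8ToInt(q) - 33), numeric(1L),
                   USE.NAMES = FALSE)
  data.frame(
    name = name,
    length = nchar(seqs),
    mean_q = mean_q,
    pass = mean_q > q_pass,
    stringsAsFactors = FALSE
  )
}

#' Write sequences as FASTQ
#'
#' Line-based writer (4 lines per record): unlike fixed-buffer FASTQ
#' writers it is safe for reads of any length.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param qualities Optional per-read integer mean quality (recycled to a
#'   constant per-base quality string); default Q20.
#' @export
write_fastq <- function(seqs, path, qualities = 20L) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("read%06d", seq_along(seqs))
  }
  qualities <- rep_len(as.integer(qualities), length(seqs))
  qchr <- strrep(vapply(qualities, function(q) rawToChar(as.raw(33L + q)),
                        character(1L)),
                 nchar(seqs))
  rec <- rbind(paste0("@", names(seqs)), unname(seqs), "+", qchr)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Accepts a 4-column bedGraph (`contig start end depth`, 0-based half-open)
#' or the 3-column `contig pos depth` dialect written by pileup tools
#' (1-based positions).
#'
#' @param path Input path.
#' @return `data.frame` with columns `contig`, `start`, `end`, `depth`.
#' @export
read_depth_track <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) == 4L) {
    names(tab) <- c("contig", "start", "end", "depth")
  } else if (ncol(tab) == 3L) {
    names(tab) <- c("contig", "pos", "depth")
    tab <- data.frame(contig = tab$contig, start = tab$pos - 1,
                      end = tab$pos, depth = tab$depth,
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognised depth track layout (expected 3 or 4 columns)")
  }
  tab
}

#' Write intervals as BED
#'
#' @param df Table with columns `contig`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1, df$end))
  if (!is.null(df$name)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
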
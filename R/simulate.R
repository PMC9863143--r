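## Seeded simulator: random references with genes, diverged haplotypes with
## truth variants, Cas9-digested fragments per a tiling plan, nanopore-like
## and Illumina-like reads. Everything needed to exercise the design, QC
## and comparison modules end-to-end without external data.

DNA_BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles every tunable of the simulator with defaults emulating the
#' study conditions this package targets: a few-hundred-kbp plant locus
#' diverged from its reference by roughly 5 SNVs and 2.5 small indels per
#' kbp, enriched as ~50-kbp Cas9 fragments and sequenced as long reads
#' with an N50 near 30 kbp and a ~5% per-base error rate (R9.4.1-like),
#' against a large excess of background fragments.
#'
#' @param genome_length Reference length in bp (default 250,000).
#' @param gc_fraction GC content (default 0.38, legume-like).
#' @param n_genes Number of non-overlapping gene features (default 30).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (default `log(3000)`, 0.4).
#' @param snv_rate,small_indel_rate Events per bp for the diverged
#'   haplotype (defaults 0.005 and 0.0025).
#' @param max_indel Maximum small-indel size in bp (default 20).
#' @param sv_list List of explicit structural variants, each
#'   `list(kind = "deletion"|"insertion", pos = <0-based>, size = <bp>)`.
#' @param cut_efficiency Per-guide probability that a cut occurs (default
#'   0.9).
#' @param background_rate Fraction of reads drawn from random genome
#'   positions rather than liberated fragments (default 0.97).
#' @param read_count Number of simulated long reads (default 5,000).
#' @param read_length_n50,read_length_sdlog Log-normal read-length model,
#'   parameterised by target N50 (default 30,000 bp) and log-sd (0.55);
#'   the log-mean is `log(n50) - sdlog^2` (the size-biased median of a
#'   log-normal is `exp(mu + sigma^2)`).
#' @param error_mismatch,error_ins,error_del Per-base read error rates
#'   (defaults 0.02, 0.01, 0.02).
#' @param end_slack Maximum bp trimmed from each liberated-fragment read
#'   end (default 150).
#' @param seed Integer seed fixing all downstream randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 250000, gc_fraction = 0.38,
                       n_genes = 30L, gene_length_meanlog = log(3000),
                       gene_length_sdlog = 0.4, snv_rate = 0.005,
                       small_indel_rate = 0.0025, max_indel = 20L,
                       sv_list = list(), cut_efficiency = 0.9,
                       background_rate = 0.97, read_count = 5000L,
                       read_length_n50 = 30000, read_length_sdlog = 0.55,
                       error_mismatch = 0.02, error_ins = 0.01,
                       error_del = 0.02, end_slack = 150L, seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$snv_rate, cfg$small_indel_rate, cfg$error_mismatch,
             cfg$error_ins, cfg$error_del)
  probs <- c(cfg$gc_fraction, cfg$cut_efficiency, cfg$background_rate)
  stopifnot(all(rates >= 0), all(probs >= 0 & probs <= 1),
            cfg$genome_length >= 1000, cfg$read_count >= 0)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a reference genome with gene features
#'
#' Random sequence at the requested GC content carrying `n_genes`
#' non-overlapping gene features (each gene paired with a CDS covering its
#' interior). Genes are placed one per equal-width slot, which guarantees
#' non-overlap; infeasible packings (gene longer than its slot) raise an
#' error. Fully reproducible under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param contig Contig name (default `"chr1"`).
#' @return List with `genome` (a `DNAStringSet`) and `genes` (a gene
#'   table as from [read_genes()]).
#' @export
make_reference <- function(config, contig = "chr1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  seqs <- Biostrings::DNAStringSet(setNames(random_dna(L, config$gc_fraction),
                                            contig))
  n <- config$n_genes
  genes <- NULL
  if (n > 0L) {
    lens <- pmax(300, round(rlnorm(n, config$gene_length_meanlog,
                                   config$gene_length_sdlog)))
    spare <- L - sum(lens) - 2 * n
    if (spare <= 0) {
      stop("gene packing infeasible: ", n, " genes totalling ", sum(lens),
           " bp do not fit in ", L, " bp")
    }
    ## stick-breaking: split the spare space into n+1 random gaps
    w <- runif(n + 1L)
    gaps <- floor(spare * w / sum(w)) + 1L
    gstart <- cumsum(c(gaps[1L],
                       if (n > 1L) lens[-n] + gaps[2:n] else numeric(0)))
    gene_id <- sprintf("gene%03d", seq_len(n))
    genes <- rbind(
      data.frame(contig = contig, start = gstart, end = gstart + lens,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 gene_id = gene_id, feature_kind = "gene",
                 stringsAsFactors = FALSE),
      data.frame(contig = contig, start = gstart, end = gstart + lens,
                 strand = "+", gene_id = paste0(gene_id, ".cds"),
                 feature_kind = "CDS", stringsAsFactors = FALSE)
    )
    genes <- genes[order(genes$start, genes$feature_kind), , drop = FALSE]
    rownames(genes) <- NULL
  }
  list(genome = seqs, genes = genes)
}

## Edits: internal representation of planted differences on one contig.
## (rstart, rend) is the replaced reference span (0-based half-open;
## rstart == rend for a pure insertion) and `alt` the replacement text.
new_edit <- function(rstart, rend, alt, kind, size) {
  data.frame(rstart = rstart, rend = rend, alt = alt, kind = kind,
             size = size, stringsAsFactors = FALSE)
}

#' Apply variants to a reference, producing a diverged haplotype
#'
#' Plants the explicit structural variants of `config$sv_list`, then random
#' small indels and SNVs at the configured per-bp rates (collisions with
#' already-occupied spans are rejection-sampled away). Returns the
#' haplotype, a truth table in VCF-anchored representation (the interval
#' spans the REF allele) and the internal edit list used for lift-over and
#' truth alignments.
#'
#' @param reference List from [make_reference()] or a `DNAStringSet`.
#' @param config A [sim_config()].
#' @return List with `haplotype` (`DNAStringSet`), `truth` (variant
#'   table), `edits` (per-contig edit list, internal).
#' @export
apply_variants <- function(reference, config) {
  genome <- if (is.list(reference) && !is.null(reference$genome))
    reference$genome else reference
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  hap <- character(length(genome))
  names(hap) <- names(genome)
  truth_all <- list()
  edits_all <- list()
  for (ct in names(genome)) {
    seq <- as.character(genome[[ct]])
    L <- nchar(seq)
    chars <- strsplit(seq, "")[[1L]]
    occupied <- logical(L)
    edits <- list()

    ## 1. explicit SVs
    for (sv in config$sv_list) {
      if (!is.null(sv$contig) && sv$contig != ct) next
      pos <- sv$pos
      size <- sv$size
      if (pos < 1 || pos + size > L) {
        stop("sv_list entry out of bounds: pos ", pos, " size ", size,
             " on contig ", ct, " of length ", L)
      }
      if (sv$kind == "deletion") {
        edits[[length(edits) + 1L]] <-
          new_edit(pos, pos + size, "", "deletion", size)
        occupied[(pos + 1):(pos + size)] <- TRUE
      } else if (sv$kind == "insertion") {
        edits[[length(edits) + 1L]] <-
          new_edit(pos, pos, random_dna(size, config$gc_fraction),
                   "insertion", size)
        occupied[pos + 1] <- TRUE
      } else {
        stop("unknown sv kind: ", sv$kind)
      }
    }

    ## 2. random small indels
    n_indel <- rbinom(1L, L, config$small_indel_rate)
    placed <- 0L
    tries <- 0L
    while (placed < n_indel && tries < 20L * n_indel + 100L) {
      tries <- tries + 1L
      size <- min(config$max_indel, rgeom(1L, 0.25) + 1L)
      pos <- sample.int(L - size - 2L, 1L)
      is_del <- runif(1L) < 0.5
      span <- if (is_del) (pos + 1):(pos + size) else pos + 1
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      edits[[length(edits) + 1L]] <- if (is_del) {
        new_edit(pos, pos + size, "", "deletion", size)
      } else {
        new_edit(pos, pos, random_dna(size, config$gc_fraction),
                 "insertion", size)
      }
      placed <- placed + 1L
    }

    ## 3. SNVs
    n_snv <- rbinom(1L, L, config$snv_rate)
    free <- which(!occupied)
    n_snv <- min(n_snv, length(free))
    if (n_snv > 0L) {
      pos1 <- sort(sample(free, n_snv))  # 1-based
      for (p in pos1) {
        refb <- chars[p]
        altb <- sample(setdiff(DNA_BASES, refb), 1L)
        edits[[length(edits) + 1L]] <-
          new_edit(p - 1L, p, altb, "SNV", 1L)
      }
      occupied[pos1] <- TRUE
    }

    edits <- if (length(edits)) do.call(rbind, edits) else
      new_edit(numeric(0), numeric(0), character(0), character(0),
               integer(0))
    edits <- edits[order(edits$rstart, edits$rend), , drop = FALSE]
    rownames(edits) <- NULL

    ## assemble haplotype: reference segments interleaved with edit alts
    pieces <- character(0)
    cursor <- 0L
    for (r in seq_len(nrow(edits))) {
      if (edits$rstart[r] > cursor) {
        pieces <- c(pieces, substr(seq, cursor + 1L, edits$rstart[r]))
      }
      pieces <- c(pieces, edits$alt[r])
      cursor <- edits$rend[r]
    }
    if (cursor < L) pieces <- c(pieces, substr(seq, cursor + 1L, L))
    hap[ct] <- paste(pieces, collapse = "")

    truth_all[[ct]] <- edits_to_truth(edits, chars, ct)
    edits_all[[ct]] <- edits
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  list(haplotype = Biostrings::DNAStringSet(hap), truth = truth,
       edits = edits_all)
}

## VCF-anchored truth records from the edit list.
edits_to_truth <- function(edits, chars, contig) {
  if (!nrow(edits)) {
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      size = integer(0), stringsAsFactors = FALSE))
  }
  n <- nrow(edits)
  start <- end <- numeric(n)
  ref <- alt <- character(n)
  for (r in seq_len(n)) {
    k <- edits$kind[r]
    if (k == "SNV") {
      start[r] <- edits$rstart[r]
      end[r] <- edits$rend[r]
      ref[r] <- chars[edits$rstart[r] + 1L]
      alt[r] <- edits$alt[r]
    } else if (k == "insertion") {
      a <- edits$rstart[r] - 1L  # anchor base, 0-based
      start[r] <- a
      end[r] <- a + 1L
      ref[r] <- chars[a + 1L]
      alt[r] <- paste0(chars[a + 1L], edits$alt[r])
    } else {
      a <- edits$rstart[r] - 1L
      start[r] <- a
      end[r] <- edits$rend[r]
      ref[r] <- paste(chars[(a + 1L):edits$rend[r]], collapse = "")
      alt[r] <- chars[a + 1L]
    }
  }
  data.frame(contig = contig, start = start, end = end, ref = ref,
             alt = alt, kind = edits$kind, size = edits$size,
             stringsAsFactors = FALSE)
}

#' Lift reference positions onto a simulated haplotype
#'
#' Piecewise-linear lift-over across the planted edit list. Positions
#' inside a deleted span map to the deletion breakpoint.
#'
#' @param positions 0-based reference positions.
#' @param edits Edit table for one contig (from [apply_variants()]
#'   `$edits`).
#' @return 0-based haplotype positions.
#' @export
lift_positions <- function(positions, edits) {
  if (!nrow(edits)) return(positions)
  delta <- cumsum(nchar(edits$alt) - (edits$rend - edits$rstart))
  out <- positions
  for (i in seq_along(positions)) {
    x <- positions[i]
    before <- which(edits$rend <= x)
    d <- if (length(before)) delta[max(before)] else 0
    inside <- which(edits$rstart < x & edits$rend > x)
    if (length(inside)) {
      j <- inside[1L]
      dprev <- if (j > 1L) delta[j - 1L] else 0
      out[i] <- edits$rstart[j] + dprev
    } else {
      out[i] <- x + d
    }
  }
  out
}

## Inverse lift: haplotype position -> reference position (approximate
## inside inserted text: maps to the insertion point).
unlift_positions <- function(positions, edits) {
  if (!nrow(edits)) return(positions)
  alt_len <- nchar(edits$alt)
  ref_len <- edits$rend - edits$rstart
  delta <- cumsum(alt_len - ref_len)
  hstart <- edits$rstart + c(0, delta[-length(delta)])
  hend <- hstart + alt_len
  out <- positions
  for (i in seq_along(positions)) {
    x <- positions[i]
    before <- which(hend <= x)
    d <- if (length(before)) delta[max(before)] else 0
    inside <- which(hstart < x & hend > x)
    if (length(inside)) {
      j <- inside[1L]
      out[i] <- edits$rstart[j] + min(x - hstart[j], ref_len[j])
    } else {
      out[i] <- x - d
    }
  }
  out
}

#' Truth alignment of a haplotype to its reference
#'
#' Builds the exact alignment implied by the planted edit list as an
#' `=`/`X`/`I`/`D` CIGAR with the matching NM value (mismatches plus
#' inserted plus deleted bases). This is the simulator's error-free truth
#' record, built directly from the edits, independent of any variant
#' caller.
#'
#' @param sim Result of [apply_variants()].
#' @param reference The reference used (list from [make_reference()] or
#'   `DNAStringSet`).
#' @param contig Contig to align (default the first).
#' @return A one-row alignment table (see [read_alignments()]).
#' @export
truth_alignment <- function(sim, reference, contig = NULL) {
  genome <- if (is.list(reference) && !is.null(reference$genome))
    reference$genome else reference
  if (is.null(contig)) contig <- names(genome)[1L]
  edits <- sim$edits[[contig]]
  L <- length(genome[[contig]])
  ops <- character(0)
  cursor <- 0L
  nm <- 0
  for (r in seq_len(nrow(edits))) {
    if (edits$rstart[r] > cursor) {
      ops <- c(ops, paste0(edits$rstart[r] - cursor, "="))
    }
    k <- edits$kind[r]
    if (k == "SNV") {
      ops <- c(ops, "1X"); nm <- nm + 1
    } else if (k == "insertion") {
      ops <- c(ops, paste0(edits$size[r], "I")); nm <- nm + edits$size[r]
    } else {
      ops <- c(ops, paste0(edits$size[r], "D")); nm <- nm + edits$size[r]
    }
    cursor <- edits$rend[r]
  }
  if (cursor < L) ops <- c(ops, paste0(L - cursor, "="))
  data.frame(
    qname = paste0(contig, "_hap"),
    query_length = length(sim$haplotype[[contig]]),
    contig = contig,
    start = 0,
    end = L,
    strand = "+",
    cigar = paste(ops, collapse = ""),
    mapq = 60L,
    nm = nm,
    stringsAsFactors = FALSE
  )
}

#' Inject sequencing errors into a read sequence
#'
#' Independent per-base mismatch / insertion / deletion errors at the
#' configured rates (no homopolymer-aware weighting).
#'
#' @param seq Character scalar.
#' @param mismatch,ins,del Per-base error probabilities.
#' @return Character scalar with errors applied.
#' @export
inject_errors <- function(seq, mismatch = 0.02, ins = 0.01, del = 0.02) {
  if (mismatch == 0 && ins == 0 && del == 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  keep <- runif(L) >= del
  chars <- chars[keep]
  L2 <- length(chars)
  if (L2 == 0L) return("")
  mm <- which(runif(L2) < mismatch)
  if (length(mm)) {
    chars[mm] <- vapply(chars[mm], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1L), USE.NAMES = FALSE)
  }
  n_ins <- rbinom(1L, L2, ins)
  if (n_ins > 0L) {
    at <- sort(sample.int(L2, n_ins, replace = TRUE))
    pieces <- character(0)
    cursor <- 0L
    for (p in at) {
      pieces <- c(pieces, paste(chars[(cursor + 1L):p], collapse = ""),
                  sample(DNA_BASES, 1L))
      cursor <- p
    }
    if (cursor < L2) {
      pieces <- c(pieces, paste(chars[(cursor + 1L):L2], collapse = ""))
    }
    return(paste(pieces, collapse = ""))
  }
  paste(chars, collapse = "")
}

#' Simulate Cas9 digestion and nanopore-like sequencing
#'
#' Each reaction pool cuts at its guides' cut sites independently with
#' probability `cut_efficiency`; a planned fragment is liberated when both
#' of its flanking cuts succeed in its own pool. Reads are then sampled:
#' with probability `background_rate` a read comes from a random genome
#' position with a log-normal length, otherwise it is a liberated fragment
#' trimmed by up to `end_slack` bp at each end. Per-read truth (origin
#' interval in reference space and on-target flag) is recorded.
#'
#' @param haplotype `DNAStringSet`, or a named vector of contig lengths
#'   when `with_sequences = FALSE` (lets large backgrounds be simulated
#'   without materialising sequence).
#' @param plan A pooled `tiling_plan` (reference coordinates).
#' @param config A [sim_config()].
#' @param edits Optional per-contig edit list from [apply_variants()];
#'   when supplied, plan cut sites are lifted onto the haplotype and read
#'   origins are mapped back to reference space.
#' @param with_sequences Emit read sequences with injected errors
#'   (default `TRUE`).
#' @return List with `reads` (truth table: `read_id`, `contig`, `start`,
#'   `end` in haplotype space, `ref_start`, `ref_end`, `origin`,
#'   `fragment`, `length`, `on_target`), `liberated` (fragment indices),
#'   and `seqs` (`DNAStringSet` or `NULL`).
#' @export
digest_and_sequence <- function(haplotype, plan, config, edits = NULL,
                                with_sequences = TRUE) {
  stopifnot(inherits(plan, "tiling_plan"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (methods::is(haplotype, "DNAStringSet")) {
    hap_len <- contig_lengths(haplotype)
  } else {
    hap_len <- haplotype
    if (with_sequences) {
      stop("with_sequences = TRUE requires sequence input, not lengths")
    }
  }
  if (anyNA(plan$subrois$pool)) {
    stop("plan has unassigned pools; run assign_pools() first")
  }

  s <- plan$subrois
  guide_cut <- setNames(plan$guides$cut_position + 1, plan$guides$id)
  lift <- function(pos, ct) {
    if (is.null(edits) || is.null(edits[[ct]])) pos
    else lift_positions(pos, edits[[ct]])
  }
  unlift <- function(pos, ct) {
    if (is.null(edits) || is.null(edits[[ct]])) pos
    else unlift_positions(pos, edits[[ct]])
  }

  ## digestion: per pool, per guide success
  cut_ok <- setNames(runif(nrow(plan$guides)) < config$cut_efficiency,
                     plan$guides$id)
  liberated <- which(cut_ok[s$left_id] & cut_ok[s$right_id])

  n <- config$read_count
  meanlog <- log(config$read_length_n50) - config$read_length_sdlog^2
  is_bg <- runif(n) < config$background_rate
  if (!length(liberated)) is_bg[] <- TRUE

  contigs <- names(hap_len)
  reads <- data.frame(
    read_id = sprintf("read%06d", seq_len(n)),
    contig = NA_character_, start = NA_real_, end = NA_real_,
    origin = ifelse(is_bg, "background", "fragment"),
    fragment = NA_integer_, stringsAsFactors = FALSE
  )

  n_bg <- sum(is_bg)
  if (n_bg > 0L) {
    bg_ct <- sample(contigs, n_bg, replace = TRUE,
                    prob = hap_len / sum(hap_len))
    bg_len <- pmin(pmax(100, round(rlnorm(n_bg, meanlog,
                                          config$read_length_sdlog))),
                   hap_len[bg_ct])
    bg_start <- floor(runif(n_bg, 0, hap_len[bg_ct] - bg_len + 1))
    reads$contig[is_bg] <- bg_ct
    reads$start[is_bg] <- bg_start
    reads$end[is_bg] <- bg_start + bg_len
  }
  n_on <- n - n_bg
  if (n_on > 0L) {
    fr <- liberated[sample.int(length(liberated), n_on, replace = TRUE)]
    ct <- s$contig[fr]
    fs <- vapply(seq_len(n_on), function(i)
      lift(guide_cut[[s$left_id[fr[i]]]], ct[i]), numeric(1L))
    fe <- vapply(seq_len(n_on), function(i)
      lift(guide_cut[[s$right_id[fr[i]]]], ct[i]), numeric(1L))
    trim_l <- floor(runif(n_on, 0, config$end_slack + 1))
    trim_r <- floor(runif(n_on, 0, config$end_slack + 1))
    rs <- pmin(fs + trim_l, fe - 1)
    re <- pmax(fe - trim_r, rs + 1)
    reads$contig[!is_bg] <- ct
    reads$start[!is_bg] <- rs
    reads$end[!is_bg] <- re
    reads$fragment[!is_bg] <- fr
  }
  reads$length <- reads$end - reads$start
  reads$ref_start <- NA_real_
  reads$ref_end <- NA_real_
  for (ct in unique(reads$contig)) {
    sel <- reads$contig == ct
    reads$ref_start[sel] <- unlift(reads$start[sel], ct)
    reads$ref_end[sel] <- unlift(reads$end[sel], ct)
  }
  reads$on_target <- reads$contig == plan$roi$contig &
    pmax(0, pmin(reads$ref_end, plan$roi$end) -
            pmax(reads$ref_start, plan$roi$start)) > 0

  seqs <- NULL
  if (with_sequences && n > 0L) {
    raw <- vapply(seq_len(n), function(i) {
      as.character(Biostrings::subseq(haplotype[[reads$contig[i]]],
                                      reads$start[i] + 1, reads$end[i]))
    }, character(1L))
    withe <- vapply(raw, inject_errors, character(1L),
                    mismatch = config$error_mismatch,
                    ins = config$error_ins, del = config$error_del,
                    USE.NAMES = FALSE)
    seqs <- Biostrings::DNAStringSet(setNames(withe, reads$read_id))
  }
  list(reads = reads, liberated = liberated, seqs = seqs)
}

#' Simulate Illumina-like paired-end reads
#'
#' Inward-facing pairs with normally distributed insert sizes, sampled to
#' an expected per-base depth equal to `coverage`.
#'
#' @param genome `DNAStringSet` (or [make_reference()] result).
#' @param coverage Target mean depth.
#' @param read_length Read length in bp (default 150).
#' @param insert_mean,insert_sd Insert-size model (defaults 400, 60).
#' @param error_rate Per-base substitution error (default 0).
#' @param seed Integer seed.
#' @param with_sequences Emit sequences (default `TRUE`).
#' @return List with `pairs` (truth table: `pair_id`, `contig`,
#'   `insert_start`, `insert_end`, `r1_start`, `r1_end`, `r2_start`,
#'   `r2_end`) and `r1`, `r2` (`DNAStringSet` or `NULL`).
#' @export
illumina_pairs <- function(genome, coverage, read_length = 150L,
                           insert_mean = 400, insert_sd = 60,
                           error_rate = 0, seed = 1L,
                           with_sequences = TRUE) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  set.seed(seed)
  lens <- contig_lengths(genome)
  G <- sum(lens)
  if (read_length > min(lens)) {
    stop("read_length (", read_length, ") exceeds the shortest contig")
  }
  n <- ceiling(coverage * G / (2 * read_length))
  ct <- sample(names(lens), n, replace = TRUE, prob = lens / G)
  ins <- pmin(pmax(read_length, round(rnorm(n, insert_mean, insert_sd))),
              lens[ct])
  start <- floor(runif(n, 0, lens[ct] - ins + 1))
  pairs <- data.frame(
    pair_id = sprintf("pair%06d", seq_len(n)),
    contig = ct, insert_start = start, insert_end = start + ins,
    r1_start = start, r1_end = pmin(start + read_length, start + ins),
    r2_start = pmax(start + ins - read_length, start),
    r2_end = start + ins,
    stringsAsFactors = FALSE
  )
  r1 <- r2 <- NULL
  if (with_sequences) {
    r1 <- vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(genome[[ct[i]]], pairs$r1_start[i] + 1,
                                      pairs$r1_end[i])), character(1L))
    r2 <- vapply(seq_len(n), function(i)
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[ct[i]]], pairs$r2_start[i] + 1,
                           pairs$r2_end[i]))), character(1L))
    if (error_rate > 0) {
      r1 <- vapply(r1, inject_errors, character(1L),
                   mismatch = error_rate, ins = 0, del = 0,
                   USE.NAMES = FALSE)
      r2 <- vapply(r2, inject_errors, character(1L),
                   mismatch = error_rate, ins = 0, del = 0,
                   USE.NAMES = FALSE)
    }
    r1 <- Biostrings::DNAStringSet(setNames(r1, paste0(pairs$pair_id, "/1")))
    r2 <- Biostrings::DNAStringSet(setNames(r2, paste0(pairs$pair_id, "/2")))
  }
  list(pairs = pairs, r1 = r1, r2 = r2)
}

#' Perfect truth alignments for simulated reads
#'
#' Converts a simulator truth table into alignment records (full-length
#' match CIGARs in reference space), the error-free alignments a perfect
#' aligner would produce. Useful for exercising the QC module without an
#' external aligner.
#'
#' @param reads Truth table from [digest_and_sequence()].
#' @param mapq Mapping quality to assign (default 60).
#' @return Alignment table (see [read_alignments()]).
#' @export
reads_to_alignments <- function(reads, mapq = 60L) {
  len <- reads$ref_end - reads$ref_start
  data.frame(
    qname = reads$read_id,
    query_length = as.integer(len),
    contig = reads$contig,
    start = reads$ref_start,
    end = reads$ref_end,
    strand = "+",
    cigar = paste0(as.integer(len), "M"),
    mapq = mapq,
    nm = 0L,
    stringsAsFactors = FALSE
  )
}
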
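## Shared fixtures and independent brute-force oracles. The oracles
## deliberately use the most literal formulation of each definition so that
## they share no code with the implementation under test.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.5, with_n = 0) {
  alphabet <- c(BASES, "N")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2, 0)
  prob <- (1 - with_n) * prob / sum(prob)
  prob[5] <- with_n
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

## Brute-force protospacer scan: slide a 23-nt window over both strands,
## test the PAM trinucleotide literally. Returns sorted (start, strand).
oracle_scan <- function(seq, sl = 20L) {
  L <- nchar(seq)
  hits <- list()
  for (s in seq_len(L - sl - 2L)) {           # 1-based window start, plus
    proto <- substr(seq, s, s + sl - 1L)
    pam <- substr(seq, s + sl, s + sl + 2L)
    if (!grepl("N", proto, fixed = TRUE) &&
        substr(pam, 1, 1) %in% BASES &&
        substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G") {
      hits[[length(hits) + 1L]] <- c(start = s - 1L, strand = "+")
    }
  }
  rc <- revcomp_chr(seq)
  for (s in seq_len(L - sl - 2L)) {           # windows on the minus strand
    proto <- substr(rc, s, s + sl - 1L)
    pam <- substr(rc, s + sl, s + sl + 2L)
    if (!grepl("N", proto, fixed = TRUE) &&
        substr(pam, 1, 1) %in% BASES &&
        substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G") {
      ## minus-strand window start s (1-based in rc) maps to plus-strand
      ## 0-based protospacer start L - (s - 1) - sl
      hits[[length(hits) + 1L]] <- c(start = L - s + 1L - sl, strand = "-")
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  df <- data.frame(start = as.integer(vapply(hits, `[[`, "", "start")),
                   strand = vapply(hits, `[[`, "", "strand"),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$strand), , drop = FALSE]
}

## Brute-force N50: try every candidate length L in the set, take the
## largest whose >=L reads hold at least half the total bases.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  ok <- vapply(sort(unique(lengths)), function(L)
    sum(lengths[lengths >= L]) >= total / 2, logical(1L))
  max(sort(unique(lengths))[ok])
}

## Brute-force per-base pileup: for every base of the interval, count the
## alignments whose M/=/X CIGAR runs cover it, base by base.
oracle_depth <- function(aln, iv_start, iv_end, mapq_min = 0L) {
  depth <- integer(iv_end - iv_start)
  for (i in seq_len(nrow(aln))) {
    if (aln$mapq[i] < mapq_min) next
    pos <- aln$start[i]  # 0-based
    ops <- regmatches(aln$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", aln$cigar[i]))[[1L]]
    for (o in ops) {
      n <- as.integer(sub("[A-Z=]", "", o))
      op <- sub("[0-9]+", "", o)
      if (op %in% c("M", "=", "X")) {
        for (p in pos:(pos + n - 1L)) {
          if (p >= iv_start && p < iv_end) {
            depth[p - iv_start + 1L] <- depth[p - iv_start + 1L] + 1L
          }
        }
        pos <- pos + n
      } else if (op %in% c("D", "N")) {
        pos <- pos + n
      }
    }
  }
  depth
}

## Brute-force Hamming occurrence count of a spacer+NGG over both strands.
oracle_match_count <- function(proto, seq, max_mm = 0L) {
  sl <- nchar(proto)
  count <- 0L
  scan_one <- function(s) {
    L <- nchar(s)
    for (p in seq_len(L - sl - 2L)) {
      win <- substr(s, p, p + sl - 1L)
      mm <- sum(strsplit(win, "")[[1L]] != strsplit(proto, "")[[1L]])
      pam <- substr(s, p + sl, p + sl + 2L)
      if (mm <= max_mm && substr(pam, 1, 1) %in% BASES &&
          substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G" &&
          !grepl("N", win, fixed = TRUE)) {
        count <<- count + 1L
      }
    }
  }
  scan_one(seq)
  scan_one(revcomp_chr(seq))
  count
}

## Direct pool-validity check, at the literal constraint granularity:
## every pool x every owned fragment x every cut site of that pool.
oracle_pool_violations <- function(plan) {
  s <- plan$subrois
  cuts <- setNames(plan$guides$cut_position + 1, plan$guides$id)
  n_viol <- 0L
  for (p in unique(s$pool)) {
    owned <- which(s$pool == p)
    pool_cuts <- cuts[unique(c(s$left_id[owned], s$right_id[owned]))]
    for (i in owned) {
      n_viol <- n_viol +
        sum(pool_cuts > s$start[i] & pool_cuts < s$end[i])
    }
  }
  n_viol
}

## Dense synthetic candidate set: one valid cut boundary every `step` bp
## across [start, end) on alternating strands.
dense_candidates <- function(contig, start, end, step = 500L) {
  cut_b <- seq(start, end, by = step)       # desired cut boundaries
  strand <- rep(c("+", "-"), length.out = length(cut_b))
  ## choose protospacer intervals producing those boundaries:
  ## plus: cut_position = start + 16 -> interval start = b - 17
  ## minus: cut_position = start + 2 -> interval start = b - 3
  ps <- ifelse(strand == "+", cut_b - 17L, cut_b - 3L)
  data.frame(
    id = sprintf("dcand%05d", seq_along(cut_b)),
    protospacer = NA_character_, pam = NA_character_,
    contig = contig, start = ps, end = ps + 20L, strand = strand,
    cut_position = cut_b - 1L,
    stringsAsFactors = FALSE
  )
}

the_panel <- function() {
  read_guide_panel(system.file("extdata", "pod_shattering_crRNAs.tsv",
                               package = "castile"))
}

the_roi <- function() parse_region_string("Chr05:38,489,481-38,723,757")
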
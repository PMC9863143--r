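test_that("the published spacer context yields its plus-strand candidate", {
  g <- read_reference(c(chr1 = paste0("AAAAA", "CTCAAGGGTCGTAACATTCC",
                                      "TGG", "AAAAA")))
  cands <- scan_protospacers(g, genomic_interval("chr1", 0, 33))
  plus <- cands[cands$strand == "+", ]
  expect_true(any(plus$protospacer == "CTCAAGGGTCGTAACATTCC" &
                  plus$pam == "TGG"))
})

test_that("sequences without GG or CC yield no candidates", {
  g <- read_reference(c(chr1 = paste(rep("AT", 200), collapse = "")))
  cands <- scan_protospacers(g, genomic_interval("chr1", 0, 400))
  expect_equal(nrow(cands), 0L)
})

test_that("regions shorter than a full site yield an empty table", {
  g <- read_reference(c(chr1 = "ACGTACGTACGTACGTACGTAC"))
  cands <- scan_protospacers(g, genomic_interval("chr1", 0, 22))
  expect_equal(nrow(cands), 0L)
})

test_that("scan agrees with the window-by-window oracle on random sequences", {
  set.seed(11)
  for (i in 1:20) {
    seq <- random_seq(500, gc = runif(1, 0.3, 0.6),
                      with_n = sample(c(0, 0.02), 1L))
    g <- read_reference(c(chr1 = seq))
    got <- scan_protospacers(g, genomic_interval("chr1", 0, 500))
    got <- got[order(got$start, got$strand), ]  # oracle orders by start
    exp <- oracle_scan(seq)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$start, exp$start)
    expect_equal(got$strand, exp$strand)
  }
})

test_that("scanning the reverse complement mirrors the candidate set", {
  set.seed(12)
  seq <- random_seq(800, gc = 0.5)
  L <- nchar(seq)
  fwd <- scan_protospacers(read_reference(c(c1 = seq)),
                           genomic_interval("c1", 0, L))
  rev <- scan_protospacers(read_reference(c(c1 = revcomp_chr(seq))),
                           genomic_interval("c1", 0, L))
  ## a plus candidate at [s, s+20) maps to a minus candidate at
  ## [L - s - 20, L - s) on the reverse complement, and vice versa
  mirrored <- data.frame(start = L - fwd$end,
                         strand = ifelse(fwd$strand == "+", "-", "+"),
                         protospacer = fwd$protospacer)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  revs <- rev[order(rev$start, rev$strand), ]
  expect_equal(revs$start, mirrored$start)
  expect_equal(revs$strand, mirrored$strand)
  expect_equal(revs$protospacer, mirrored$protospacer)
})

test_that("blunt cut sites sit 3 bp from the PAM on both strands", {
  ## published guides: plus-strand gRNA.1 cuts between 38,489,497/498,
  ## minus-strand gRNA.2 between 38,540,896/897 (1-based)
  panel <- the_panel()
  expect_equal(panel$cut_position[panel$id == "gRNA.1"], 38489496)
  expect_equal(panel$cut_position[panel$id == "gRNA.2"], 38540895)

  ## protospacer at 1-based 1-20, plus strand: cut between 17 and 18
  origin <- data.frame(start = 0, end = 20, strand = "+")
  expect_equal(cut_site(origin), 16)

  ## property over a scanned set: cut strictly inside the protospacer and
  ## exactly 3 bp from the PAM-proximal end
  set.seed(13)
  g <- read_reference(c(c1 = random_seq(1500)))
  cands <- scan_protospacers(g, genomic_interval("c1", 0, 1500))
  cut <- cut_site(cands)
  expect_true(all(cut > cands$start & cut < cands$end - 1))
  plus <- cands$strand == "+"
  expect_true(all(cut[plus] == cands$end[plus] - 4))
  expect_true(all(cut[!plus] == cands$start[!plus] + 2))
})

test_that("genome-wide match counting honours planted sites and mismatch budgets", {
  set.seed(14)
  proto <- "ACGTTGCAACGGATCGATTG"
  filler <- function(n) random_seq(n, gc = 0.5)
  site <- paste0(proto, "TGG")

  one <- read_reference(c(c1 = paste0(filler(200), site, filler(200))))
  expect_equal(count_genomic_matches(proto, one), 1L)

  two <- read_reference(c(c1 = paste0(filler(200), site, filler(150), site,
                                      filler(100))))
  expect_equal(count_genomic_matches(proto, two), 2L)

  ## second site at Hamming distance 1 and 2
  p1 <- proto; substr(p1, 5, 5) <- "A"   # T -> A, one mismatch
  p2 <- p1; substr(p2, 10, 10) <- "T"    # two mismatches
  g1 <- read_reference(c(c1 = paste0(filler(150), site, filler(100),
                                     p1, "AGG", filler(80))))
  expect_equal(count_genomic_matches(proto, g1, max_mismatches = 0L), 1L)
  expect_equal(count_genomic_matches(proto, g1, max_mismatches = 1L), 2L)
  g2 <- read_reference(c(c1 = paste0(filler(150), site, filler(100),
                                     p2, "AGG", filler(80))))
  expect_equal(count_genomic_matches(proto, g2, max_mismatches = 1L), 1L)

  ## random genomes against the brute-force Hamming oracle
  for (i in 1:10) {
    seq <- paste0(filler(120), site, filler(sample(200:400, 1L)))
    mm <- sample(0:1, 1L)
    expect_equal(
      count_genomic_matches(proto, read_reference(c(c1 = seq)),
                            max_mismatches = mm),
      oracle_match_count(proto, seq, max_mm = mm)
    )
  }
})

## A small locus with genes, depth and variants for filter tests:
## candidates are scanned, then criteria toggled by construction.
make_filter_fixture <- function() {
  set.seed(15)
  seq <- random_seq(3000, gc = 0.5)
  g <- read_reference(c(c1 = seq))
  region <- genomic_interval("c1", 0, 3000)
  cands <- scan_protospacers(g, region)
  genes <- data.frame(contig = "c1", start = 0, end = 3000, strand = "+",
                      gene_id = "g1", feature_kind = "gene",
                      stringsAsFactors = FALSE)
  depth <- structure(list(interval = region,
                          depth = rep(30L, 3000), mapq_min = 1L),
                     class = "depth_profile")
  list(genome = g, region = region, cands = cands, genes = genes,
       depth = depth)
}

test_that("candidates failing each criterion are flagged, passers pass", {
  fx <- make_filter_fixture()
  cands <- head(fx$cands, 5L)

  ## an SNV planted inside candidate 2's footprint
  fp2 <- if (cands$strand[2] == "+") cands$start[2] else cands$start[2] - 3
  variants <- data.frame(contig = "c1", start = fp2 + 1, end = fp2 + 2,
                         ref = "A", alt = "G", kind = "SNV",
                         stringsAsFactors = FALSE)
  out <- filter_candidates(cands, fx$genes, variants, fx$depth,
                           genome = fx$genome)
  expect_false(out$variant_free[2])
  expect_false(out$pass[2])
  expect_true(all(out$in_gene))

  ## all-pass construction: in gene, depth 30, no variants, unique sites
  clean <- filter_candidates(cands, fx$genes,
                             variants[0, , drop = FALSE], fx$depth,
                             genome = fx$genome)
  unique_ok <- clean$unique
  expect_true(all(clean$pass == (clean$in_gene & clean$covered &
                                 clean$variant_free & unique_ok)))
  expect_true(any(clean$pass))
})

test_that("a planted fixture passes exactly the candidates built to pass", {
  fx <- make_filter_fixture()
  cands <- head(fx$cands, 5L)
  ## shrink the gene so only candidates 1 and 3 fit inside; keep depth high
  fps <- castile:::candidate_footprint(cands)
  genes <- data.frame(
    contig = "c1",
    start = c(fps$start[1], fps$start[3]),
    end = c(fps$end[1], fps$end[3]),
    strand = "+", gene_id = c("gA", "gB"), feature_kind = "gene",
    stringsAsFactors = FALSE)
  out <- filter_candidates(cands, genes, NULL, fx$depth,
                           genome = fx$genome)
  expect_equal(which(out$in_gene), c(1L, 3L))
  expect_lte(sum(out$pass), 2L)
  expect_true(all(which(out$pass) %in% c(1L, 3L)))
})

test_that("low depth fails coverage, and filtering is monotone", {
  fx <- make_filter_fixture()
  cands <- head(fx$cands, 8L)
  shallow <- fx$depth
  shallow$depth[1:500] <- 3L
  base <- filter_candidates(cands, fx$genes, NULL, shallow,
                            genome = fx$genome, min_depth = 5L)
  stricter <- filter_candidates(cands, fx$genes, NULL, shallow,
                                genome = fx$genome, min_depth = 31L)
  expect_true(all(which(stricter$pass) %in% which(base$pass)))
  expect_equal(sum(stricter$pass), 0L)

  ## adding variants never grows the PASS set
  more_vars <- data.frame(contig = "c1", start = cands$start[1] + 5,
                          end = cands$start[1] + 6, ref = "A", alt = "T",
                          kind = "SNV", stringsAsFactors = FALSE)
  with_vars <- filter_candidates(cands, fx$genes, more_vars, shallow,
                                 genome = fx$genome, min_depth = 5L)
  expect_true(all(which(with_vars$pass) %in% which(base$pass)))

  ## footprint outside the depth profile fails with a warning, not an error
  off <- cands[1, ]
  off$start <- 5000; off$end <- 5020; off$cut_position <- 5016
  expect_warning(
    res <- filter_candidates(off, fx$genes, NULL, fx$depth,
                             genome = NULL),
    "depth"
  )
  expect_false(res$covered)
})
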
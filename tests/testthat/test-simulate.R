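test_that("reference simulation is seeded, GC-true and packs genes", {
  cfg <- sim_config(genome_length = 100000, gc_fraction = 0.5, seed = 7L)
  a <- make_reference(cfg)
  b <- make_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))

  cfg_gc <- sim_config(genome_length = 1000000, gc_fraction = 0.35,
                       n_genes = 0L, seed = 8L)
  g <- make_reference(cfg_gc)$genome
  freq <- Biostrings::alphabetFrequency(g, collapse = TRUE)
  gc <- (freq[["G"]] + freq[["C"]]) / sum(freq[c("A", "C", "G", "T")])
  expect_lt(abs(gc - 0.35), 0.01)

  genes <- a$genes[a$genes$feature_kind == "gene", ]
  expect_equal(nrow(genes), cfg$n_genes)
  ord <- genes[order(genes$start), ]
  expect_true(all(ord$start[-1] >= head(ord$end, -1)))  # non-overlapping

  ## infeasible packing is an error, not silent overlap
  cramped <- sim_config(genome_length = 5000, n_genes = 10L,
                        gene_length_meanlog = log(3000), seed = 9L)
  expect_error(make_reference(cramped), "packing")
})

test_that("zero rates leave the haplotype identical with an empty truth set", {
  cfg <- sim_config(genome_length = 20000, snv_rate = 0,
                    small_indel_rate = 0, n_genes = 3L, seed = 10L)
  ref <- make_reference(cfg)
  sim <- apply_variants(ref, cfg)
  expect_identical(as.character(sim$haplotype), as.character(ref$genome))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a planted 3,325-bp deletion shortens the haplotype exactly", {
  cfg <- sim_config(genome_length = 50000, snv_rate = 0,
                    small_indel_rate = 0, n_genes = 3L,
                    sv_list = list(list(kind = "deletion", pos = 20000,
                                        size = 3325)),
                    seed = 11L)
  ref <- make_reference(cfg)
  sim <- apply_variants(ref, cfg)
  expect_equal(length(sim$haplotype[[1]]),
               length(ref$genome[[1]]) - 3325L)
  expect_equal(sim$truth$kind, "deletion")
  expect_equal(sim$truth$size, 3325L)
})

test_that("haplotype length bookkeeping holds with mixed variant classes", {
  cfg <- sim_config(genome_length = 60000, snv_rate = 0.004,
                    small_indel_rate = 0.002, n_genes = 5L,
                    sv_list = list(list(kind = "insertion", pos = 10000,
                                        size = 500)),
                    seed = 12L)
  ref <- make_reference(cfg)
  sim <- apply_variants(ref, cfg)
  ins <- sum(sim$truth$size[sim$truth$kind == "insertion"])
  del <- sum(sim$truth$size[sim$truth$kind == "deletion"])
  expect_equal(length(sim$haplotype[[1]]),
               length(ref$genome[[1]]) + ins - del)
  ## truth is sorted and VCF-writable/readable
  expect_true(!is.unsorted(sim$truth$start))
  vcf <- tempfile(fileext = ".vcf")
  write_variants_vcf(sim$truth, vcf)
  back <- read_variants(vcf)
  expect_equal(nrow(back), nrow(sim$truth))
  expect_equal(back$kind, sim$truth$kind)

  ## out-of-bounds SVs are rejected
  bad <- sim_config(genome_length = 10000, n_genes = 0L,
                    sv_list = list(list(kind = "deletion", pos = 9000,
                                        size = 2000)), seed = 13L)
  expect_error(apply_variants(make_reference(bad), bad), "out of bounds")
})

test_that("SNV counts concentrate at the configured rate", {
  cfg <- sim_config(genome_length = 200000, snv_rate = 0.005,
                    small_indel_rate = 0, n_genes = 0L, seed = 14L)
  sim <- apply_variants(make_reference(cfg), cfg)
  n <- sum(sim$truth$kind == "SNV")
  ## binomial: mean 1000, sd ~31.6; accept +/- 3 sigma
  expect_gt(n, 1000 - 95)
  expect_lt(n, 1000 + 95)
})

test_that("lift-over round-trips positions across planted edits", {
  cfg <- sim_config(genome_length = 30000, snv_rate = 0.003,
                    small_indel_rate = 0.002, n_genes = 0L,
                    sv_list = list(list(kind = "deletion", pos = 12000,
                                        size = 800)),
                    seed = 15L)
  ref <- make_reference(cfg)
  sim <- apply_variants(ref, cfg)
  edits <- sim$edits[[1]]
  set.seed(15)
  pos <- sort(sample(0:29999, 200))
  ## positions outside deleted spans must round-trip exactly
  in_del <- vapply(pos, function(p)
    any(edits$kind == "deletion" & edits$rstart < p & edits$rend > p),
    logical(1L))
  lifted <- lift_positions(pos, edits)
  back <- castile:::unlift_positions(lifted, edits)
  expect_equal(back[!in_del], pos[!in_del])
  ## lifted sequence context agrees: the base at a lifted SNV-free match
  ## position is unchanged between reference and haplotype
  clear <- pos[!in_del & !pos %in% edits$rstart]
  refc <- substring(as.character(ref$genome[[1]]), clear + 1, clear + 1)
  hapc <- substring(as.character(sim$haplotype[[1]]),
                    lift_positions(clear, edits) + 1,
                    lift_positions(clear, edits) + 1)
  expect_equal(hapc, refc)
})

## a small end-to-end scenario reused by the digestion tests
digestion_scenario <- function(read_count, seed, cut_efficiency = 1,
                               background_rate = 0,
                               error_mismatch = 0, error_ins = 0,
                               error_del = 0, with_sequences = TRUE) {
  cfg <- sim_config(genome_length = 120000, n_genes = 10L, snv_rate = 0,
                    small_indel_rate = 0, cut_efficiency = cut_efficiency,
                    background_rate = background_rate,
                    read_count = read_count, read_length_n50 = 20000,
                    error_mismatch = error_mismatch, error_ins = error_ins,
                    error_del = error_del, seed = seed)
  ref <- make_reference(cfg)
  roi <- genomic_interval("chr1", 10000, 110000)
  cands <- dense_candidates("chr1", 5000, 115000, step = 400L)
  plan <- assign_pools(plan_tiling(roi, cands, target_length = 40000))
  sim <- digest_and_sequence(ref$genome, plan, cfg,
                             with_sequences = with_sequences)
  list(cfg = cfg, ref = ref, roi = roi, plan = plan, sim = sim)
}

test_that("full cutting without background yields only fragment reads", {
  sc <- digestion_scenario(read_count = 120, seed = 16L)
  reads <- sc$sim$reads
  expect_true(all(reads$origin == "fragment"))
  s <- sc$plan$subrois
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    fr <- reads$fragment[i]
    reads$ref_start[i] >= s$start[fr] && reads$ref_end[i] <= s$end[fr]
  }, logical(1L))
  expect_true(all(ok))
  expect_true(all(reads$on_target))
})

test_that("error-free reads are exact substrings of the source sequence", {
  sc <- digestion_scenario(read_count = 25, seed = 17L)
  reads <- sc$sim$reads
  for (i in seq_len(nrow(reads))) {
    expect_identical(
      as.character(sc$sim$seqs[[i]]),
      as.character(Biostrings::subseq(sc$ref$genome[[reads$contig[i]]],
                                      reads$start[i] + 1, reads$end[i]))
    )
  }
})

test_that("digestion and read sampling are byte-reproducible under a seed", {
  a <- digestion_scenario(read_count = 40, seed = 18L, background_rate = 0.5)
  b <- digestion_scenario(read_count = 40, seed = 18L, background_rate = 0.5)
  expect_identical(a$sim$reads, b$sim$reads)
  expect_identical(as.character(a$sim$seqs), as.character(b$sim$seqs))

  fq <- tempfile(fileext = ".fastq")
  write_fastq(a$sim$seqs, fq, qualities = 12L)
  fq2 <- tempfile(fileext = ".fastq")
  write_fastq(b$sim$seqs, fq2, qualities = 12L)
  expect_identical(readLines(fq), readLines(fq2))
})

test_that("failed cuts suppress their fragments; zero cutting gives background only", {
  sc <- digestion_scenario(read_count = 60, seed = 19L,
                           cut_efficiency = 0.5, background_rate = 0,
                           with_sequences = FALSE)
  lib <- sc$sim$liberated
  frag <- sc$sim$reads$fragment
  expect_true(all(is.na(frag) | frag %in% lib))  # NA: background fallback
  if (length(lib) > 0 && length(lib) < nrow(sc$plan$subrois)) {
    expect_true(all(na.omit(frag) %in% lib))
  }

  none <- digestion_scenario(read_count = 30, seed = 20L,
                             cut_efficiency = 0, background_rate = 0,
                             with_sequences = FALSE)
  expect_equal(length(none$sim$liberated), 0L)
  expect_true(all(none$sim$reads$origin == "background"))
})

test_that("read lengths follow the configured N50 target", {
  cfg <- sim_config(genome_length = 1000, n_genes = 0L,
                    read_length_n50 = 30000, read_length_sdlog = 0.55,
                    seed = 21L)
  set.seed(21)
  meanlog <- log(cfg$read_length_n50) - cfg$read_length_sdlog^2
  lens <- round(rlnorm(20000, meanlog, cfg$read_length_sdlog))
  ## the size-biased median of the log-normal is exp(mu + sigma^2) = N50
  expect_lt(abs(read_n50(lens) - 30000) / 30000, 0.05)
})

test_that("nanopore truth tables feed QC: recovered fraction matches planted truth", {
  sc <- digestion_scenario(read_count = 400, seed = 22L,
                           background_rate = 0.8, with_sequences = FALSE)
  aln <- reads_to_alignments(sc$sim$reads)
  cls <- classify_on_target(aln, sc$roi)
  expect_equal(cls$on_target, sc$sim$reads$on_target)
  expect_equal(cls$on_count, sum(sc$sim$reads$on_target))
})

test_that("Illumina pair simulation hits the requested coverage", {
  cfg <- sim_config(genome_length = 200000, n_genes = 0L, seed = 23L)
  ref <- make_reference(cfg)
  sim <- illumina_pairs(ref, coverage = 24.6, read_length = 150L,
                        seed = 23L, with_sequences = FALSE)
  p <- sim$pairs
  aln <- data.frame(
    qname = c(paste0(p$pair_id, "/1"), paste0(p$pair_id, "/2")),
    query_length = 150L, contig = p$contig,
    start = c(p$r1_start, p$r2_start), end = c(p$r1_end, p$r2_end),
    strand = c(rep("+", nrow(p)), rep("-", nrow(p))),
    cigar = NA_character_, mapq = 60L, nm = 0L, stringsAsFactors = FALSE)
  md <- mean_depth(aln, genomic_interval("chr1", 0, 200000))
  expect_lt(abs(md - 24.6) / 24.6, 0.05)

  ## deep coverage makes every base callable
  deep <- illumina_pairs(ref$genome, coverage = 40, seed = 24L,
                         with_sequences = FALSE)
  dp <- deep$pairs
  daln <- data.frame(
    qname = c(paste0(dp$pair_id, "/1"), paste0(dp$pair_id, "/2")),
    query_length = 150L, contig = dp$contig,
    start = c(dp$r1_start, dp$r2_start), end = c(dp$r1_end, dp$r2_end),
    strand = "+", cigar = NA_character_, mapq = 60L, nm = 0L,
    stringsAsFactors = FALSE)
  ## coverage decays toward contig ends, so judge the interior
  prof <- depth_profile(daln, genomic_interval("chr1", 2000, 198000))
  expect_equal(genotypability(prof, 5), 100)

  ## determinism and error bounds
  again <- illumina_pairs(ref, coverage = 24.6, read_length = 150L,
                          seed = 23L, with_sequences = FALSE)
  expect_identical(again$pairs, sim$pairs)
  expect_error(illumina_pairs(ref, coverage = 5, read_length = 500000L),
               "contig")
})

test_that("pairs carry inward-facing sequences from the genome", {
  cfg <- sim_config(genome_length = 5000, n_genes = 0L, seed = 25L)
  ref <- make_reference(cfg)
  sim <- illumina_pairs(ref, coverage = 2, read_length = 100L, seed = 25L)
  p <- sim$pairs[1, ]
  expect_identical(
    as.character(sim$r1[[1]]),
    as.character(Biostrings::subseq(ref$genome[[1]], p$r1_start + 1,
                                    p$r1_end)))
  expect_identical(
    as.character(sim$r2[[1]]),
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(ref$genome[[1]], p$r2_start + 1, p$r2_end))))
})

test_that("the design-to-comparison pipeline round-trips on simulated data", {
  ## design guides on a simulated reference, plan, digest, QC, compare
  cfg <- sim_config(genome_length = 80000, n_genes = 12L, snv_rate = 0.002,
                    small_indel_rate = 0.0005, cut_efficiency = 1,
                    background_rate = 0, read_count = 60,
                    read_length_n50 = 15000, error_mismatch = 0,
                    error_ins = 0, error_del = 0,
                    sv_list = list(list(kind = "deletion", pos = 40000,
                                        size = 1200)),
                    seed = 26L)
  ref <- make_reference(cfg)
  roi <- genomic_interval("chr1", 5000, 75000)
  cands <- scan_protospacers(ref$genome, roi)
  sim <- apply_variants(ref, cfg)
  flt <- filter_candidates(cands, ref$genes, sim$truth, depth = NULL,
                           genome = ref$genome)
  pass <- flt[flt$in_gene & flt$variant_free & flt$unique, ]
  expect_gt(nrow(pass), 10L)

  plan <- assign_pools(plan_tiling(roi, pass, target_length = 25000,
                                   overlap_min = 500, overlap_max = 4000,
                                   boundary_window = 5000))
  expect_equal(nrow(validate_plan(plan)), 0L)
  expect_equal(oracle_pool_violations(plan), 0L)

  dig <- digest_and_sequence(sim$haplotype, plan, cfg, edits = sim$edits,
                             with_sequences = FALSE)
  expect_true(all(dig$reads$on_target))

  ## planted variants recovered exactly from the truth alignment
  ta <- truth_alignment(sim, ref)
  calls <- call_variants(ta, query_seq = sim$haplotype[[1]],
                         target_seq = ref$genome[[1]])
  truth <- sim$truth
  expect_equal(sum(calls$kind == "SNV"), sum(truth$kind == "SNV"))
  expect_equal(sum(calls$kind == "insertion"),
               sum(truth$kind == "insertion"))
  expect_equal(sum(calls$kind == "deletion"),
               sum(truth$kind == "deletion"))
  expect_true(any(calls$is_sv & calls$size == 1200))
})
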
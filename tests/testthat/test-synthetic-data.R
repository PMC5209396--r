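# Generators: transcriptome pair, diversity panel, alpha design, trial.

test_that("transcriptome pair plants exactly the recorded SNPs", {
  sim <- simulate_transcriptome_pair(n_contigs = 1, contig_length = 1000,
                                     snp_rate = 1 / 1000, seed = 42)
  a <- sim$consensus_a[[1]]$bases
  b <- sim$consensus_b[[1]]$bases
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_setequal(diff_pos, sim$truth$position)
  expect_true(all(sim$truth$allele_a != sim$truth$allele_b))
  # accession A equals the reference
  expect_identical(a, unname(sim$reference[sim$consensus_a[[1]]$contig_id]))
})

test_that("zero SNP rate gives identical consensus pairs and no truth", {
  sim <- simulate_transcriptome_pair(n_contigs = 3, contig_length = 300,
                                     snp_rate = 0, seed = 1)
  for (cid in names(sim$consensus_a)) {
    expect_identical(sim$consensus_a[[cid]]$bases,
                     sim$consensus_b[[cid]]$bases)
  }
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(discover_snps(sim$consensus_a, sim$consensus_b)), 0)
})

test_that("same seed reproduces byte-identical FASTA/FASTQ output", {
  d1 <- file.path(tempdir(), "tp1"); d2 <- file.path(tempdir(), "tp2")
  s1 <- simulate_transcriptome_pair(n_contigs = 10, contig_length = 400,
                                    snp_rate = 0.01, paralog_rate = 0.2,
                                    low_quality_rate = 0.05, seed = 99,
                                    out_dir = d1)
  s2 <- simulate_transcriptome_pair(n_contigs = 10, contig_length = 400,
                                    snp_rate = 0.01, paralog_rate = 0.2,
                                    low_quality_rate = 0.05, seed = 99,
                                    out_dir = d2)
  for (f in c("reference.fasta", "consensus_A.fastq", "consensus_B.fastq")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_identical(s1$truth, s2$truth)
})

test_that("paralog copies stay above the declared identity", {
  sim <- simulate_transcriptome_pair(n_contigs = 10, contig_length = 500,
                                     snp_rate = 0.005, paralog_rate = 0.3,
                                     paralog_identity = 0.99, seed = 7)
  expect_gt(nrow(sim$paralogs), 0)
  expect_true(all(sim$paralogs$identity >= 0.98))
  # planted truth marks SNPs whose host contig has a paralog
  hosts <- unique(sim$paralogs$paralog_of)
  expect_true(all(sim$truth$on_paralog_source ==
                    (sim$truth$contig_id %in% hosts)))
})

test_that("contigs shorter than a fragment are rejected", {
  expect_error(simulate_transcriptome_pair(contig_length = 149, seed = 1),
               "150 nt")
})

test_that("low-quality sites get Phred below 33, others the default", {
  sim <- simulate_transcriptome_pair(n_contigs = 2, contig_length = 300,
                                     snp_rate = 0.01,
                                     low_quality_rate = 0.1, seed = 5)
  for (cid in names(sim$consensus_a)) {
    ph <- sim$consensus_a[[cid]]$phred
    lq <- sim$low_quality_sites[[cid]]
    if (length(lq)) expect_true(all(ph[lq] < 33))
    expect_true(all(ph[setdiff(seq_along(ph), lq)] == 40))
  }
})

test_that("consensus FASTQ round-trips through Biostrings", {
  sim <- simulate_transcriptome_pair(n_contigs = 3, contig_length = 200,
                                     snp_rate = 0.01,
                                     low_quality_rate = 0.05, seed = 11)
  fq <- tempfile(fileext = ".fastq")
  write_consensus_fastq(sim$consensus_a, fq)
  back <- read_consensus_fastq(fq, accession = "A")
  for (cid in names(sim$consensus_a)) {
    expect_identical(back[[cid]]$bases, sim$consensus_a[[cid]]$bases)
    expect_identical(back[[cid]]$phred, sim$consensus_a[[cid]]$phred)
  }
})

test_that("diversity panel matches its configuration", {
  cfg <- panel_sim_config(n_accessions = 96, n_markers = 653, fst = 0.25,
                          het_rate = 0.02, missing_rate = 0.01, seed = 21)
  ps <- simulate_diversity_panel(cfg)
  expect_equal(dim(ps$genotypes), c(96, 653))
  expect_true(all(ps$genotypes %in% c("AA", "AB", "BB") |
                    is.na(ps$genotypes)))
  expect_true(all(abs(rowSums(ps$Q_truth) - 1) < 1e-9))
  # realized heterozygosity within 3 binomial SEs of the target rate
  n_calls <- sum(!is.na(ps$genotypes))
  het <- mean(ps$genotypes == "AB", na.rm = TRUE)
  se <- sqrt(0.02 * 0.98 / n_calls)
  expect_lt(abs(het - 0.02), 3 * se)
  # map well-formed
  expect_true(all(ps$map$chrom %in% 1:10))
  expect_true(all(ps$map$pos >= 1))
})

test_that("het_rate zero produces no heterozygous calls", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 30, n_markers = 50, het_rate = 0, seed = 2))
  expect_false(any(ps$genotypes == "AB", na.rm = TRUE))
})

test_that("subpopulation frequencies collapse onto the ancestral p as Fst -> 0", {
  cfg <- panel_sim_config(n_accessions = 10, n_markers = 200,
                          n_subpops = 3, fst = 1e-4, seed = 3)
  ps <- simulate_diversity_panel(cfg)
  dev <- abs(sweep(ps$subpop_freqs, 2, ps$ancestral_p))
  expect_lt(max(dev), 0.05)
})

test_that("fst outside (0,1) is rejected", {
  expect_error(panel_sim_config(fst = 0), "fst")
  expect_error(panel_sim_config(fst = 1.2), "fst")
})

test_that("alpha design satisfies its contract at the trial geometry", {
  d <- generate_alpha_design(96, 2, 8, 12, seed = 31)
  expect_equal(nrow(d), 192)                 # every line twice overall
  expect_true(all(table(d$line) == 2))
  expect_true(all(table(d$replicate, d$line) == 1))
  expect_lte(max(design_concurrence(d)), 2)
})

test_that("ten-replicate design keeps pair concurrence at two or less", {
  d <- generate_alpha_design(96, 10, 8, 12, seed = 8)
  expect_equal(nrow(d), 960)
  expect_true(all(table(d$line) == 10))
  cc <- design_concurrence(d)               # exhaustive enumeration
  expect_lte(max(cc), 2)
})

test_that("single-replicate concurrence is at most one", {
  d <- generate_alpha_design(24, 1, 4, 6, seed = 4)
  expect_lte(max(design_concurrence(d)), 1)
})

test_that("capacity violations raise an informative error", {
  expect_error(generate_alpha_design(97, 2, 8, 12, seed = 1), "capacity")
})

test_that("trial with no variance and no QTLs is constant", {
  d <- generate_alpha_design(12, 2, 3, 4, seed = 1)
  cfg <- trial_sim_config(n_lines = 12, n_replicates = 2,
                          blocks_per_replicate = 3, pots_per_block = 4,
                          polygenic_var = 0, rep_var = 0, block_var = 0,
                          resid_var = 0, seed = 1)
  tr <- simulate_aphid_trial(d, cfg)
  expect_equal(length(unique(tr$total)), 1)
  expect_true(all(tr$alate + tr$apterous == tr$total))
  expect_true(all(tr$total >= 0))
})

test_that("grand mean total lands near the calibration target", {
  d <- generate_alpha_design(96, 10, 8, 12, seed = 13)
  ps <- simulate_diversity_panel(panel_sim_config(seed = 14))
  g <- ps$genotypes
  rownames(g) <- sprintf("line%03d", seq_len(nrow(g)))
  tr <- simulate_aphid_trial(d, trial_sim_config(seed = 15), genotypes = g)
  expect_lt(abs(mean(tr$total) - 132.327) / 132.327, 0.10)
})

test_that("a planted QTL shifts genotype-group means in its direction", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 60, n_markers = 40, seed = 16))
  g <- ps$genotypes
  rownames(g) <- sprintf("line%03d", seq_len(nrow(g)))
  af <- allele_frequencies(g)
  mk <- af$marker[which.min(abs(af$p - 0.5))]   # informative marker
  d <- generate_alpha_design(60, 4, 6, 10, seed = 17)
  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- trial_sim_config(n_lines = 60, n_replicates = 4,
                            blocks_per_replicate = 6, pots_per_block = 10,
                            qtl_markers = data.frame(marker = mk, effect = 2),
                            polygenic_var = 0.5, resid_var = 1, seed = 100 + s)
    tr <- simulate_aphid_trial(d, cfg, genotypes = g)
    code <- geno_codes(g[, mk])
    line_mean <- tapply(sqrt_transform(tr$total), tr$line, mean)
    keep <- !is.na(code) & code %in% c(0, 2)
    m0 <- mean(line_mean[names(code)[keep & code == 0]])
    m2 <- mean(line_mean[names(code)[keep & code == 2]])
    if (m2 > m0) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("unknown QTL marker ids are rejected", {
  d <- generate_alpha_design(12, 2, 3, 4, seed = 1)
  g <- matrix("AA", 12, 2,
              dimnames = list(sprintf("line%03d", 1:12), c("m1", "m2")))
  cfg <- trial_sim_config(n_lines = 12, n_replicates = 2,
                          blocks_per_replicate = 3, pots_per_block = 4,
                          qtl_markers = data.frame(marker = "nope",
                                                   effect = 1), seed = 1)
  expect_error(simulate_aphid_trial(d, cfg, genotypes = g), "nope")
})
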
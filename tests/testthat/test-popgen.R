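# Marker diagnostics: frequencies, PIC, HWE, LD, partition, distances.

test_that("allele frequencies, heterozygosity and missingness count correctly", {
  g <- matrix(c("AA", "AA", "AA", "AA", "BB", "BB", "BB", "BB",
                "AA", "AB", "AB", "BB",
                "AA", "AA", "AA", NA),
              nrow = 4,
              dimnames = list(paste0("a", 1:4), c("m1", "m2", "m3", "m4")))
  af <- allele_frequencies(g)
  expect_equal(af$p_a[af$marker == "m1"], 1)    # m1 = 4 x AA
  expect_equal(af$het_obs[af$marker == "m1"], 0)
  expect_equal(af$p[af$marker == "m2"], 1)      # all BB -> major allele freq 1
  expect_equal(af$p_a[af$marker == "m3"], 0.5)  # 1 AA, 2 AB, 1 BB
  expect_equal(af$het_obs[af$marker == "m3"], 0.5)
  expect_equal(af$p_a[af$marker == "m4"], 1)    # 3 AA, 1 NA
  expect_equal(af$missing[af$marker == "m4"], 0.25)
})

test_that("eight balanced homozygotes give p = 0.5", {
  g <- matrix(c(rep("AA", 4), rep("BB", 4)), ncol = 1,
              dimnames = list(paste0("a", 1:8), "m"))
  af <- allele_frequencies(g)
  expect_equal(af$p, 0.5)
  expect_equal(af$het_obs, 0)
})

test_that("PIC matches hand-evaluated values and its symmetry/maximum", {
  expect_identical(pic(0.5), 0.375)
  expect_identical(pic(1), 0)
  expect_equal(pic(0.9), 1 - 0.82 - 2 * 0.81 * 0.01)   # 0.1638
  grid <- seq(0, 1, by = 0.01)
  expect_equal(pic(grid), pic(1 - grid))               # symmetric
  expect_true(all(pic(grid) <= 0.375 + 1e-12))
  expect_equal(grid[which.max(pic(grid))], 0.5)
})

test_that("HWE exact test reproduces full-enumeration values", {
  r <- hwe_exact(1, 2, 1, n_permutations = 0)
  expect_equal(r$p_exact, 1)                           # observed is the mode
  expect_equal(sort(r$support$prob),
               sort(c(6, 48, 16) / 70), tolerance = 1e-12)
  r2 <- hwe_exact(2, 0, 2, n_permutations = 0)
  expect_equal(r2$p_exact, 6 / 70, tolerance = 1e-12)
  # monomorphic convention
  expect_equal(hwe_exact(10, 0, 0, n_permutations = 0)$p_exact, 1)
})

test_that("HWE enumeration probabilities always sum to one", {
  set.seed(4)
  for (i in 1:20) {
    na <- sample(0:40, 1); nb <- sample(0:40, 1)
    if ((na + nb) %% 2 == 1) nb <- nb + 1
    if (na + nb == 0) next
    expect_equal(sum(hwe_enumerate(na, nb)$prob), 1, tolerance = 1e-9)
  }
})

test_that("permutation estimator converges to the exact p-value", {
  r <- hwe_exact(30, 20, 46, n_permutations = 10000, seed = 42)
  se <- sqrt(r$p_exact * (1 - r$p_exact) / 10000)
  expect_lt(abs(r$p_perm - r$p_exact), 3 * se + 2e-4)
})

test_that("exact HWE p-values are super-uniform under random mating", {
  set.seed(11)
  m <- 250; n <- 96
  p <- stats::runif(m, 0.1, 0.9)
  pv <- vapply(seq_len(m), function(j) {
    g <- stats::rbinom(n, 2, p[j])
    hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2),
              n_permutations = 0)$p_exact
  }, 0)
  frac <- mean(pv <= 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
})

test_that("LD r2 equals the hand-computed haplotype value", {
  # haplotype counts AB:3 Ab:1 aB:0 ab:4 over 8 inbred lines
  g_i <- c(rep("BB", 4), rep("AA", 4))
  g_j <- c(rep("BB", 3), "AA", rep("AA", 4))
  expect_equal(ld_r2(g_i, g_j), 0.6, tolerance = 1e-12)
  # duplicated marker
  expect_equal(ld_r2(g_i, g_i), 1)
  # undefined cases
  expect_true(is.na(ld_r2(rep("AA", 8), g_j)))          # monomorphic
  expect_true(is.na(ld_r2(c("AA", "AB"), c("BB", "AB")))) # < 2 pairs
})

test_that("r2 equals squared Pearson correlation of allele codes", {
  set.seed(12)
  for (i in 1:10) {
    n <- 40
    x <- sample(c(0, 2), n, TRUE); y <- sample(c(0, 2), n, TRUE)
    gi <- c("AA", "AB", "BB")[x + 1]; gj <- c("AA", "AB", "BB")[y + 1]
    got <- ld_r2(gi, gj)
    want <- suppressWarnings(stats::cor(x, y)^2)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("independent markers have mean r2 near 1/n", {
  set.seed(13)
  n <- 50; m <- 60
  codes <- matrix(sample(c(0, 2), n * m, TRUE), n,
                  dimnames = list(paste0("a", 1:n), paste0("m", 1:m)))
  g <- geno_from_codes(codes)
  ld <- pairwise_ld(g)
  expect_equal(mean(ld$r2, na.rm = TRUE), 1 / n, tolerance = 0.3)
})

test_that("LD decays with distance on simulated linked blocks", {
  set.seed(14)
  n <- 80; m <- 40
  # blocks of 8 markers share a latent haplotype with decreasing fidelity
  base <- matrix(sample(c(0, 2), n * 5, TRUE), n, 5)
  codes <- matrix(0, n, m)
  for (j in seq_len(m)) {
    blk <- (j - 1) %/% 8 + 1
    off <- (j - 1) %% 8
    flip <- stats::runif(n) < 0.05 * off
    codes[, j] <- ifelse(flip, 2 - base[, blk], base[, blk])
  }
  dimnames(codes) <- list(paste0("a", 1:n), sprintf("m%02d", 1:m))
  map <- data.frame(marker = sprintf("m%02d", 1:m),
                    chrom = rep(1:5, each = 8),
                    pos = rep(seq(1e5, 8e5, by = 1e5), 5))
  ld <- pairwise_ld(geno_from_codes(codes), map)
  decay <- ld_decay_table(ld, breaks = c(0, 2e5, 4e5, 8e5))
  expect_equal(nrow(decay), 3)
  expect_true(all(diff(decay$mean_r2) < 0))
  expect_true(all(decay$n_pairs > 0))
  # single chromosome, 2 markers -> one pair in one bin
  ld2 <- pairwise_ld(geno_from_codes(codes[, 1:2]), map[1:2, ])
  d2 <- ld_decay_table(ld2, breaks = c(0, 2e5))
  expect_equal(sum(d2$n_pairs), 1)
  # all markers on distinct chromosomes -> empty table with warning
  map3 <- data.frame(marker = sprintf("m%02d", 1:5), chrom = 1:5,
                     pos = 1e5)
  ld3 <- pairwise_ld(geno_from_codes(codes[, 1:5]), map3)
  expect_warning(d3 <- ld_decay_table(ld3), "no linked")
  expect_equal(nrow(d3), 0)
})

test_that("polymorphism partition reproduces the truncated percentages", {
  # 6 markers: 1 mono overall, 2 wild-mono/crop-poly, 1 wild-poly/crop-mono,
  # 1 alternate-fixed, 1 poly in both
  g <- cbind(
    m1 = rep("AA", 8),
    m2 = c(rep("AA", 4), "AA", "AA", "AB", "BB"),
    m3 = c(rep("BB", 4), "AA", "BB", "AA", "BB"),
    m4 = c("AA", "AB", "BB", "AA", rep("BB", 4)),
    m5 = c(rep("AA", 4), rep("BB", 4)),
    m6 = c("AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB"))
  rownames(g) <- paste0("a", 1:8)
  groups <- rep(c("wild", "crop"), each = 4)
  part <- partition_polymorphism(g, groups)
  expect_equal(part$counts[["monomorphic_overall"]], 1L)
  expect_equal(part$counts[["wild_mono_crop_poly"]], 2L)
  expect_equal(part$counts[["wild_poly_crop_mono"]], 1L)
  expect_equal(part$counts[["alternate_fixed"]], 1L)
  expect_equal(part$counts[["poly_in_both"]], 1L)
  expect_equal(part$n_polymorphic, 5L)
  expect_equal(part$percents[["wild_mono_crop_poly"]],
               trunc(100 * 2 / 5 * 100) / 100)
  # all-polymorphic matrix: every special category zero
  g2 <- cbind(m1 = rep(c("AA", "BB"), 4), m2 = rep(c("BB", "AA"), 4))
  rownames(g2) <- paste0("a", 1:8)
  p2 <- partition_polymorphism(g2, groups)
  expect_equal(unname(p2$counts[c("monomorphic_overall",
                                  "wild_mono_crop_poly",
                                  "wild_poly_crop_mono",
                                  "alternate_fixed")]),
               rep(0L, 4))
  expect_error(partition_polymorphism(g, rep("crop", 8)), "wild")
})

test_that("percentage truncation reproduces 244 of 653 as 37.36", {
  expect_equal(truncate_percent(100 * 244 / 653), 37.36)
})

test_that("intermarker distances are per-chromosome gaps with global stats", {
  map <- data.frame(marker = c("a", "b", "c", "d", "e", "f"),
                    chrom = c(1, 1, 1, 2, 10, 10),
                    pos = c(100, 154, 1000, 5000, 1, 2))
  d <- intermarker_distances(map)
  expect_equal(sort(d$gaps$gap_bp), c(54, 846))   # group 10 excluded,
  expect_equal(d$min_bp, 54)                      # single marker on chr2
  expect_equal(d$max_bp, 846)
  expect_equal(d$n_gaps, 2L)
  # printed coordinates of the linked flanking-marker pair
  expect_equal(206512113 - 206453742, 58371)
  map2 <- data.frame(marker = c("x", "y"), chrom = c(8, 8),
                     pos = c(206453742, 206512113))
  expect_equal(intermarker_distances(map2)$min_bp, 58371)
})

test_that("het filter drops loci above 20% bad calls, strictly", {
  n <- 100
  mk_col <- function(n_bad) c(rep("AB", n_bad), rep("AA", n - n_bad))
  g <- cbind(m_over = mk_col(21),   # 21% > 20% -> dropped
             m_exact = mk_col(20),  # exactly 20% -> kept (strict ">")
             m_clean = rep(c("AA", "BB"), n / 2))
  rownames(g) <- paste0("a", 1:n)
  hf <- het_filter(g)
  expect_equal(hf$dropped_loci, "m_over")
  expect_true(all(c("m_exact", "m_clean") %in% colnames(hf$genotypes)))
  # surviving heterozygotes recoded missing
  expect_true(all(is.na(hf$genotypes[1:20, "m_exact"])))
  # clean matrix passes through unchanged
  hf2 <- het_filter(g[, "m_clean", drop = FALSE])
  expect_identical(hf2$genotypes, g[, "m_clean", drop = FALSE])
})
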
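# KW scan, VanRaden kinship, EMMA REML, mixed-model scan, intersection.

test_that("KW scan reproduces the hand-computed two-group statistic", {
  y <- stats::setNames(c(1, 2, 3, 4), paste0("a", 1:4))
  g <- matrix(c("AA", "AA", "BB", "BB"), 4, 1,
              dimnames = list(paste0("a", 1:4), "m1"))
  out <- kw_scan(y, g)
  expect_equal(out$kw_H, 2.4, tolerance = 1e-9)
  expect_equal(out$kw_p, stats::pchisq(2.4, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("KW conventions: ties, monomorphic and small classes", {
  y <- stats::setNames(rep(5, 6), paste0("a", 1:6))
  g <- matrix(c(rep("AA", 3), rep("BB", 3)), 6, 1,
              dimnames = list(paste0("a", 1:6), "m1"))
  out <- kw_scan(y, g)
  expect_equal(out$kw_H, 0)
  expect_equal(out$kw_p, 1)
  g2 <- matrix(rep("AA", 6), 6, 1, dimnames = dimnames(g))
  expect_true(kw_scan(y, g2)$skipped)
  g3 <- matrix(c("AA", rep("BB", 5)), 6, 1, dimnames = dimnames(g))
  expect_equal(kw_scan(y, g3)$reason, "class too small")
  # heterozygotes are excluded from the two-class comparison
  y4 <- stats::setNames(c(1, 2, 9, 3, 4), paste0("a", 1:5))
  g4 <- matrix(c("AA", "AA", "AB", "BB", "BB"), 5, 1,
               dimnames = list(paste0("a", 1:5), "m1"))
  expect_equal(kw_scan(y4, g4)$kw_H, 2.4, tolerance = 1e-9)
})

test_that("chi-square KW p tracks the exact permutation p where the test decides", {
  # exhaustive over every achievable statistic for n = 7, 8: in the
  # significance region (either p <= 0.1) the chi-square approximation
  # is within 0.05 of the exact permutation tail probability; outside
  # it the discrete null makes a continuous approximation necessarily
  # coarser
  for (n in 7:8) {
    for (n1 in 2:(n %/% 2)) {
      y <- stats::setNames(as.numeric(seq_len(n)), paste0("a", seq_len(n)))
      idx <- utils::combn(n, n1)
      for (col in seq_len(ncol(idx))) {
        gcode <- rep(2, n); gcode[idx[, col]] <- 0
        g <- matrix(c("AA", "AB", "BB")[gcode + 1], n, 1,
                    dimnames = list(names(y), "m"))
        p_chi <- kw_scan(y, g)$kw_p
        p_perm <- kw_perm_oracle(y, gcode)
        if (min(p_chi, p_perm) <= 0.1) {
          expect_lt(abs(p_chi - p_perm), 0.05)
        }
      }
    }
  }
})

test_that("VanRaden kinship matches hand arithmetic and its properties", {
  g <- matrix(c(0, 2, 0, 2), 2, 2,
              dimnames = list(c("x", "y"), c("m1", "m2")))
  K <- vanraden_kinship(g)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # duplicated accession: off-diagonal equals both diagonals
  set.seed(4)
  codes <- matrix(sample(c(0, 2), 20 * 50, TRUE, prob = c(.4, .6)), 20)
  codes <- rbind(codes, codes[1, ])
  dimnames(codes) <- list(paste0("a", 1:21), paste0("m", 1:50))
  K2 <- vanraden_kinship(codes)
  expect_equal(K2[1, 21], K2[1, 1], tolerance = 1e-9)
  expect_equal(K2[1, 21], K2[21, 21], tolerance = 1e-9)
  # symmetric PSD
  expect_equal(K2, t(K2), tolerance = 1e-12)
  expect_gt(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # fully inbred panel: diagonal near 1 + F = 2
  expect_equal(mean(diag(K2)), 2, tolerance = 0.35)
  expect_error(vanraden_kinship(matrix(0, 3, 2)), "monomorphic")
})

test_that("with identity kinship the mixed-model scan collapses to OLS", {
  set.seed(5)
  n <- 40; m <- 25
  codes <- matrix(sample(0:2, n * m, TRUE), n,
                  dimnames = list(paste0("a", 1:n), paste0("m", 1:m)))
  y <- stats::setNames(stats::rnorm(n), rownames(codes))
  g <- geno_from_codes(codes)
  mm <- suppressWarnings(mm_scan(y, g, Q = NULL, kinship = diag(n)))
  ols_p <- vapply(seq_len(m), function(j) {
    x <- codes[, j]
    if (stats::var(x) == 0) return(NA_real_)
    summary(stats::lm(y ~ x))$coefficients["x", 4]
  }, 0)
  keep <- !is.na(ols_p) & !mm$skipped
  expect_equal(mm$mm_p[keep], ols_p[keep], tolerance = 1e-6)
})

test_that("EMMA recovers the variance ratio on structured data", {
  n <- 200
  # pure block kinship (20 families of 10) keeps s2_g and s2_e separable
  grp <- rep(1:20, each = n / 20)
  K <- outer(grp, grp, "==") * 1
  ratios <- vapply(1:20, function(s) {
    set.seed(100 + s)
    u <- stats::rnorm(20, 0, sqrt(2))[grp]       # var(u) = 2 K
    y <- 1 + u + stats::rnorm(n)                 # s2_g / s2_e = 2
    fit <- suppressWarnings(emma_reml(y, matrix(1, n, 1), K))
    fit$sigma2_g / fit$sigma2_e
  }, 0)
  expect_gt(stats::median(ratios), 1.4)
  expect_lt(stats::median(ratios), 2.8)
})

test_that("noise-free responses collapse the residual variance", {
  set.seed(7)
  n <- 30
  X <- cbind(1, stats::rnorm(n))
  y <- as.numeric(X %*% c(2, 3))          # exactly in the column space
  fit <- suppressWarnings(emma_reml(y, X, diag(n)))
  expect_lt(fit$sigma2_g + fit$sigma2_e, 1e-8)
  # pure genetic signal along a structured kinship: the variance ratio
  # runs to the grid edge and is flagged
  grp <- rep(1:10, each = 3)
  K <- outer(grp, grp, "==") * 1
  yg <- stats::rnorm(10)[grp]
  expect_warning(fitg <- emma_reml(yg, matrix(1, 30, 1), K),
                 "grid boundary")
  expect_true(fitg$boundary)
})

test_that("a planted QTL is the top mixed-model hit in most seeds", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 96, n_markers = 650, seed = 5))
  af <- allele_frequencies(ps$genotypes)
  informative <- af$marker[af$p > 0.5 & af$p < 0.7]
  kin <- vanraden_kinship(ps$genotypes)
  n_seeds <- 20; hits <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(200 + s)
    mk <- sample(informative, 1)
    code <- geno_codes(ps$genotypes[, mk])
    code[is.na(code)] <- mean(code, na.rm = TRUE)
    y <- stats::setNames(code / 2 + stats::rnorm(96), rownames(ps$genotypes))
    mm <- suppressWarnings(mm_scan(y, ps$genotypes, Q = ps$Q_truth,
                                   kinship = kin))
    if (mm$marker[which.min(mm$mm_p)] == mk) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("Q+K genomic control deflates the structured-null inflation factor", {
  n_seeds <- 10
  lam_with <- lam_without <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    ps <- simulate_diversity_panel(panel_sim_config(
      n_accessions = 96, n_markers = 300, seed = 300 + s))
    set.seed(s)
    u <- ps$Q_truth %*% stats::rnorm(3, 0, 2)
    y <- stats::setNames(as.numeric(u) + stats::rnorm(96),
                         rownames(ps$genotypes))
    kin <- vanraden_kinship(ps$genotypes)
    mm1 <- suppressWarnings(mm_scan(y, ps$genotypes, Q = ps$Q_truth,
                                    kinship = kin))
    mm0 <- suppressWarnings(mm_scan(y, ps$genotypes, Q = NULL,
                                    kinship = diag(96)))
    lam_with[s] <- genomic_lambda(mm1$mm_p)
    lam_without[s] <- genomic_lambda(mm0$mm_p)
  }
  expect_true(all(lam_without > lam_with))
  expect_gt(stats::median(lam_with), 0.9)
  expect_lt(stats::median(lam_with), 1.1)
})

test_that("P3D and exact per-marker refits agree closely", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 50, n_markers = 40, seed = 9))
  set.seed(10)
  y <- stats::setNames(stats::rnorm(50), rownames(ps$genotypes))
  kin <- vanraden_kinship(ps$genotypes)
  m1 <- suppressWarnings(mm_scan(y, ps$genotypes, Q = ps$Q_truth,
                                 kinship = kin, p3d = TRUE))
  m2 <- suppressWarnings(mm_scan(y, ps$genotypes, Q = ps$Q_truth,
                                 kinship = kin, p3d = FALSE))
  keep <- !m1$skipped & !m2$skipped
  expect_gt(stats::cor(-log10(m1$mm_p[keep]), -log10(m2$mm_p[keep])), 0.98)
})

test_that("association records obey the dual-filter flags", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 60, n_markers = 80, seed = 11))
  set.seed(12)
  y <- stats::setNames(stats::rnorm(60), rownames(ps$genotypes))
  rec <- suppressWarnings(assoc_scan(y, ps$genotypes, Q = ps$Q_truth))
  expect_true(all(rec$passes_both == (rec$passes_kw & rec$passes_mm)))
  expect_true(all(rec$marker[rec$passes_both] %in%
                    rec$marker[rec$passes_kw]))
  expect_true(all(rec$marker[rec$passes_both] %in%
                    rec$marker[rec$passes_mm]))
})

test_that("intersection report counts hits and overlaps per trait", {
  rec <- data.frame(marker = paste0("m", 1:6),
                    kw_H = 1, kw_p = c(1e-4, 1e-4, 1e-4, 0.5, 0.5, 1e-4),
                    mm_beta = 1, mm_se = 1, mm_t = 1,
                    mm_p = c(1e-3, 1e-3, 0.5, 1e-3, 0.5, 1e-3))
  rec$passes_kw <- rec$kw_p <= 0.005
  rec$passes_mm <- rec$mm_p <= 0.01
  rec$passes_both <- rec$passes_kw & rec$passes_mm
  recs <- list(alate = rec, apterous = rec[c(2:6, 1), ], total = rec)
  map <- data.frame(marker = paste0("m", 1:6), chrom = c(1, 1, 2, 2, 3, 3),
                    pos = c(10, 5, 10, 5, 10, 5))
  rep_out <- intersect_and_report(recs, map)
  expect_equal(unname(rep_out$counts), c(3L, 3L, 3L))
  expect_setequal(rep_out$shared_all, c("m1", "m2", "m6"))
  # manhattan table sorted by chromosome then position
  man <- rep_out$manhattan[rep_out$manhattan$trait == "alate", ]
  expect_equal(man$marker, c("m2", "m1", "m4", "m3", "m6", "m5"))
  # qq expected column is monotone
  qq <- rep_out$qq[rep_out$qq$trait == "alate", ]
  expect_true(all(diff(qq$expected) <= 0))
  # disjoint and identical record sets
  rec0 <- rec; rec0$passes_both <- FALSE
  expect_equal(length(intersect_and_report(list(a = rec, b = rec0))$shared_all), 0)
  same <- intersect_and_report(list(a = rec, b = rec))
  expect_setequal(same$shared_all, rec$marker[rec$passes_both])
})

test_that("permuting the trait destroys dual-test hits", {
  ps <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 96, n_markers = 200, seed = 13))
  af <- allele_frequencies(ps$genotypes)
  mk <- af$marker[which.min(abs(af$p - 0.6))]
  code <- geno_codes(ps$genotypes[, mk])
  code[is.na(code)] <- mean(code, na.rm = TRUE)
  set.seed(14)
  y <- stats::setNames(1.5 * code / 2 + stats::rnorm(96),
                       rownames(ps$genotypes))
  rec <- suppressWarnings(assoc_scan(y, ps$genotypes, Q = ps$Q_truth))
  expect_true(rec$passes_both[rec$marker == mk])
  yp <- stats::setNames(sample(y), names(y))
  recp <- suppressWarnings(assoc_scan(yp, ps$genotypes, Q = ps$Q_truth))
  expect_lte(sum(recp$passes_both), sum(rec$passes_both))
})
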
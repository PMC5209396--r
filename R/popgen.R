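# Marker-level diagnostics for a biallelic genotype matrix: allele
# frequencies, PIC, heterozygosity, LD r2 and its decay with physical
# distance, polymorphism partition between accession groups, and
# intermarker distances.

#' Per-marker allele frequencies, heterozygosity and missingness
#'
#' Allele frequency is computed from genotype counts,
#' p = (2 n_AA + n_AB) / (2 n_called), and oriented to the major
#' allele; missing calls are excluded from the denominator.
#'
#' @param genotypes accession x marker character matrix of AA/AB/BB/NA.
#' @return data.frame: marker, n_AA, n_AB, n_BB, n_called, missing
#'   (fraction), p_a (A-allele frequency), p (major-allele frequency),
#'   het_obs, all_missing.
#' @export
allele_frequencies <- function(genotypes) {
  stopifnot(is.matrix(genotypes))
  n_AA <- colSums(genotypes == "AA", na.rm = TRUE)
  n_AB <- colSums(genotypes == "AB", na.rm = TRUE)
  n_BB <- colSums(genotypes == "BB", na.rm = TRUE)
  n_called <- n_AA + n_AB + n_BB
  p_a <- ifelse(n_called > 0, (2 * n_AA + n_AB) / (2 * n_called), NA_real_)
  data.frame(
    marker = colnames(genotypes),
    n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, n_called = n_called,
    missing = 1 - n_called / nrow(genotypes),
    p_a = p_a,
    p = pmax(p_a, 1 - p_a),
    het_obs = ifelse(n_called > 0, n_AB / n_called, NA_real_),
    all_missing = n_called == 0,
    row.names = NULL
  )
}

#' Polymorphism information content of a biallelic marker
#'
#' Botstein's formula, which for a biallelic locus with allele
#' frequencies p and q = 1 - p reduces to
#' PIC = 1 - (p^2 + q^2) - 2 p^2 q^2.  The maximum, 0.375, is attained
#' at p = 0.5; the value is symmetric in p and 1 - p.
#'
#' @param p allele frequency (either allele), vectorized.
#' @return PIC values in [0, 0.375].
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' LD r-squared between two biallelic markers in an inbred panel
#'
#' Heterozygous and missing calls are dropped pairwise; the remaining
#' homozygotes are read directly as haplotypes (valid for an unphased
#' inbred panel).  r2 = D^2 / (pA (1-pA) pB (1-pB)), identically the
#' squared Pearson correlation of the 0/1 allele codes.
#'
#' @param g_i,g_j genotype call vectors (AA/AB/BB/NA) for two markers.
#' @return r2 in [0, 1], or NA when fewer than 2 complete homozygous
#'   pairs remain or either marker is monomorphic after dropping.
#' @export
ld_r2 <- function(g_i, g_j) {
  x <- geno_codes(g_i) / 2
  y <- geno_codes(g_j) / 2
  keep <- !is.na(x) & !is.na(y) & x %in% c(0, 1) & y %in% c(0, 1)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' All pairwise LD r-squared values with physical distances
#'
#' @param genotypes accession x marker call matrix.
#' @param map optional marker map (marker, chrom, pos).  Pairs on the
#'   same placed chromosome get a `distance_bp`; pairs on different
#'   chromosomes, or involving the unplaced group, are flagged
#'   `unlinked`.
#' @param unplaced_chrom chromosome label treated as unplaced
#'   (default 10).
#' @return data.frame: marker_i, marker_j, r2, distance_bp, unlinked.
#' @export
pairwise_ld <- function(genotypes, map = NULL, unplaced_chrom = 10) {
  codes <- geno_codes(genotypes) / 2
  codes[codes == 0.5] <- NA  # heterozygotes dropped
  cc <- suppressWarnings(stats::cor(codes, use = "pairwise.complete.obs"))
  r2 <- cc^2
  m <- ncol(genotypes)
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  out <- data.frame(marker_i = colnames(genotypes)[idx[, 1]],
                    marker_j = colnames(genotypes)[idx[, 2]],
                    r2 = r2[idx])
  if (!is.null(map)) {
    mi <- match(out$marker_i, map$marker)
    mj <- match(out$marker_j, map$marker)
    same <- map$chrom[mi] == map$chrom[mj] &
      map$chrom[mi] != unplaced_chrom & map$chrom[mj] != unplaced_chrom
    out$distance_bp <- ifelse(same, abs(map$pos[mi] - map$pos[mj]),
                              NA_integer_)
    out$unlinked <- !same
  }
  out
}

#' Mean LD by physical-distance bin
#'
#' Only same-chromosome pairs with a defined distance contribute;
#' unplaced-group markers are excluded upstream by [pairwise_ld()].
#'
#' @param ld data.frame from [pairwise_ld()] (needs r2, distance_bp).
#' @param breaks distance bin edges in bp.
#' @return data.frame: bin label, lower, upper, n_pairs, mean_r2.
#' @export
ld_decay_table <- function(ld,
                           breaks = c(0, 1e5, 1e6, 5e6, 1e7, 5e7, Inf)) {
  linked <- ld[!is.na(ld$distance_bp) & !is.na(ld$r2), , drop = FALSE]
  if (nrow(linked) == 0) {
    warning("no linked marker pairs with defined distances", call. = FALSE)
    return(data.frame(bin = character(), lower = numeric(),
                      upper = numeric(), n_pairs = integer(),
                      mean_r2 = numeric()))
  }
  bins <- cut(linked$distance_bp, breaks = breaks, include.lowest = TRUE)
  agg_n <- tapply(linked$r2, bins, length)
  agg_m <- tapply(linked$r2, bins, mean)
  data.frame(bin = levels(bins),
             lower = breaks[-length(breaks)],
             upper = breaks[-1],
             n_pairs = as.integer(ifelse(is.na(agg_n), 0, agg_n)),
             mean_r2 = as.numeric(agg_m),
             row.names = NULL)
}

#' Partition polymorphism between wild and crop accession groups
#'
#' Markers are classified by the alleles observed (a heterozygous call
#' contributes both alleles) in each group: monomorphic overall;
#' monomorphic in the wild group but polymorphic in the crop group;
#' the reverse; fixed for alternate alleles in the two groups; or
#' polymorphic in both.  Percentages are over the polymorphic markers
#' and truncated to two decimals (the package's reporting convention).
#'
#' @param genotypes accession x marker call matrix.
#' @param groups character vector "wild"/"crop" named by (or aligned
#'   with) the accessions.
#' @return list: counts (named integer), percents (over polymorphic
#'   markers, truncated to 2 dp), n_markers, n_polymorphic.
#' @export
partition_polymorphism <- function(genotypes, groups) {
  stopifnot(length(groups) == nrow(genotypes))
  groups <- as.character(groups)
  if (!all(groups %in% c("wild", "crop"))) {
    stop('`groups` must only contain "wild" and "crop"', call. = FALSE)
  }
  if (!any(groups == "wild") || !any(groups == "crop")) {
    stop("both a wild and a crop group are required", call. = FALSE)
  }
  alleles_of <- function(calls) {
    calls <- calls[!is.na(calls)]
    out <- character(0)
    if (any(calls %in% c("AA", "AB"))) out <- c(out, "A")
    if (any(calls %in% c("BB", "AB"))) out <- c(out, "B")
    out
  }
  m <- ncol(genotypes)
  cls <- character(m)
  for (j in seq_len(m)) {
    aw <- alleles_of(genotypes[groups == "wild", j])
    ac <- alleles_of(genotypes[groups == "crop", j])
    all_al <- union(aw, ac)
    if (length(all_al) <= 1) {
      cls[j] <- "monomorphic_overall"
    } else if (length(aw) <= 1 && length(ac) == 2) {
      cls[j] <- "wild_mono_crop_poly"
    } else if (length(aw) == 2 && length(ac) <= 1) {
      cls[j] <- "wild_poly_crop_mono"
    } else if (length(aw) == 1 && length(ac) == 1) {
      cls[j] <- "alternate_fixed"
    } else {
      cls[j] <- "poly_in_both"
    }
  }
  cats <- c("monomorphic_overall", "wild_mono_crop_poly",
            "wild_poly_crop_mono", "alternate_fixed", "poly_in_both")
  counts <- stats::setNames(vapply(cats, function(k) sum(cls == k), 0L), cats)
  n_poly <- m - counts[["monomorphic_overall"]]
  pct_cats <- setdiff(cats, "monomorphic_overall")
  percents <- if (n_poly > 0) {
    truncate_percent(100 * counts[pct_cats] / n_poly)
  } else {
    stats::setNames(rep(NA_real_, length(pct_cats)), pct_cats)
  }
  list(counts = counts, percents = percents,
       n_markers = m, n_polymorphic = as.integer(n_poly),
       classes = stats::setNames(cls, colnames(genotypes)))
}

#' Intermarker physical distances
#'
#' Gaps between consecutive markers per placed chromosome, and global
#' summary statistics over all gaps.  The unplaced group is excluded.
#'
#' @param map marker map (marker, chrom, pos).
#' @param exclude_chrom chromosome(s) to exclude (default the unplaced
#'   group 10).
#' @return list: gaps (data.frame chrom, gap_bp), mean_bp, min_bp,
#'   max_bp, n_gaps.  Duplicate positions yield zero gaps (kept).
#' @export
intermarker_distances <- function(map, exclude_chrom = 10) {
  keep <- !(map$chrom %in% exclude_chrom)
  gaps <- do.call(rbind, lapply(split(map$pos[keep], map$chrom[keep]),
                                function(p) {
    if (length(p) < 2) return(NULL)
    data.frame(gap_bp = diff(sort(p)))
  }))
  if (is.null(gaps) || nrow(gaps) == 0) {
    return(list(gaps = data.frame(chrom = integer(), gap_bp = integer()),
                mean_bp = NA_real_, min_bp = NA_real_, max_bp = NA_real_,
                n_gaps = 0L))
  }
  chroms <- rep(names(split(map$pos[keep], map$chrom[keep])),
                vapply(split(map$pos[keep], map$chrom[keep]),
                       function(p) max(length(p) - 1L, 0L), 0L))
  out <- data.frame(chrom = as.integer(chroms), gap_bp = gaps$gap_bp)
  if (any(out$gap_bp == 0)) {
    message(sum(out$gap_bp == 0), " duplicate marker position(s) (zero gaps)")
  }
  list(gaps = out, mean_bp = mean(out$gap_bp), min_bp = min(out$gap_bp),
       max_bp = max(out$gap_bp), n_gaps = nrow(out))
}

#' Filter loci with excess heterozygous/uncertain/missing calls
#'
#' Loci where heterozygous, uncertain (non AA/AB/BB) or missing calls
#' exceed `max_bad_fraction` of accessions (strict ">") are dropped;
#' heterozygous and uncertain calls in the surviving loci are recoded
#' as missing.  Optionally, accessions exceeding the same threshold
#' (after locus filtering) are dropped too.
#'
#' @param genotypes accession x marker call matrix.
#' @param max_bad_fraction locus threshold, default 0.20.
#' @param accession_max_bad_fraction optional accession-level threshold
#'   (NULL = keep all accessions).
#' @return list: genotypes (filtered, AB/uncertain recoded NA),
#'   dropped_loci, dropped_accessions, report (per-locus bad fraction).
#' @export
het_filter <- function(genotypes, max_bad_fraction = 0.20,
                       accession_max_bad_fraction = NULL) {
  bad <- is.na(genotypes) | !(genotypes %in% c("AA", "BB"))
  dim(bad) <- dim(genotypes)
  locus_bad <- colMeans(bad)
  drop_loci <- locus_bad > max_bad_fraction
  kept <- genotypes[, !drop_loci, drop = FALSE]
  kept[is.na(kept) | !(kept %in% c("AA", "BB"))] <- NA_character_
  dropped_acc <- character(0)
  if (!is.null(accession_max_bad_fraction)) {
    acc_bad <- rowMeans(is.na(kept))
    dropped_acc <- rownames(kept)[acc_bad > accession_max_bad_fraction]
    kept <- kept[!(rownames(kept) %in% dropped_acc), , drop = FALSE]
  }
  list(genotypes = kept,
       dropped_loci = colnames(genotypes)[drop_loci],
       dropped_accessions = dropped_acc,
       report = data.frame(marker = colnames(genotypes),
                           bad_fraction = locus_bad,
                           dropped = drop_loci, row.names = NULL))
}
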
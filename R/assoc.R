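# Dual marker-trait association on accession-level predicted means:
# a Kruskal-Wallis rank scan over the two homozygote classes, and an
# EMMA-style kinship mixed model with Q covariates (Q+K genomic
# control).  Hits must pass both tests.

#' Kruskal-Wallis scan over all markers
#'
#' Per marker, the two homozygote classes are compared on the trait
#' (heterozygous and missing calls dropped); the tie-corrected H
#' statistic is referred to chi-square with 1 df.  Markers with fewer
#' than `min_class_n` accessions in either class are skipped; when all
#' trait values are tied H = 0 and p = 1 by convention.
#'
#' @param trait named numeric vector of per-accession trait values
#'   (predicted means).
#' @param genotypes accession x marker call matrix; rownames must cover
#'   `names(trait)`.
#' @param min_class_n minimum class size (default 2).
#' @return data.frame: marker, n_AA, n_BB, kw_H, kw_p, skipped, reason.
#' @export
kw_scan <- function(trait, genotypes, min_class_n = 2) {
  stopifnot(!is.null(names(trait)),
            all(names(trait) %in% rownames(genotypes)))
  G <- genotypes[names(trait), , drop = FALSE]
  res <- lapply(seq_len(ncol(G)), function(j) {
    g <- geno_codes(G[, j])
    keep <- !is.na(g) & g %in% c(0, 2) & !is.na(trait)
    gg <- g[keep]; yy <- trait[keep]
    n0 <- sum(gg == 0); n2 <- sum(gg == 2)
    rec <- data.frame(marker = colnames(G)[j], n_AA = n0, n_BB = n2,
                      kw_H = NA_real_, kw_p = NA_real_,
                      skipped = FALSE, reason = NA_character_)
    if (n0 == 0 || n2 == 0) {
      rec$skipped <- TRUE; rec$reason <- "monomorphic"
    } else if (n0 < min_class_n || n2 < min_class_n) {
      rec$skipped <- TRUE; rec$reason <- "class too small"
    } else if (length(unique(yy)) == 1) {
      rec$kw_H <- 0; rec$kw_p <- 1
    } else {
      kt <- stats::kruskal.test(yy, factor(gg))
      rec$kw_H <- unname(kt$statistic)
      rec$kw_p <- kt$p.value
    }
    rec
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' VanRaden genomic relationship matrix
#'
#' Method 1: K = Z Z' / (2 sum p_j (1 - p_j)) with Z = M - 2P, M the
#' 0/1/2 allele-dosage matrix (missing imputed to 2 p_j) and p_j the
#' allele-B frequency.  Monomorphic markers are excluded.  For fully
#' inbred lines the diagonal approaches 1 + F = 2.
#'
#' @param genotypes accession x marker call (or dosage) matrix.
#' @return symmetric PSD kinship matrix with accession dimnames.
#' @export
vanraden_kinship <- function(genotypes) {
  M <- if (is.character(genotypes)) geno_codes(genotypes) else genotypes
  p <- colMeans(M, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) {
    stop("all markers are monomorphic; kinship undefined", call. = FALSE)
  }
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(M))) {
    M[is.na(M[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  K
}

# restricted log-likelihood of the rotated model at ratio delta =
# sigma2_e / sigma2_g, profiled over sigma2_g and beta
emma_restricted_ll <- function(log_delta, yt, Xt, d, logdet_xx) {
  delta <- exp(log_delta)
  w <- d + delta
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / sqrt(w)
  yw <- yt / sqrt(w)
  xx <- crossprod(Xw)
  beta <- solve(xx, crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  rss <- sum(r^2)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(w)) +
            determinant(xx, logarithm = TRUE)$modulus - logdet_xx)
}

#' EMMA-style REML variance components for the kinship mixed model
#'
#' Model y = X beta + u + e with var(u) = s2_g K, var(e) = s2_e I.
#' K is eigendecomposed once; the restricted log-likelihood is profiled
#' down to the single ratio delta = s2_e / s2_g and maximized on a log
#' grid followed by local refinement.  The returned rotation is reused
#' by the marker scan (P3D).
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (n x p, full column rank).
#' @param K kinship matrix (n x n, PSD).
#' @param log_delta_range,n_grid search grid for log delta.
#' @return list (`emma_fit`): sigma2_g, sigma2_e, delta, loglik,
#'   boundary (TRUE when the optimum sits at a grid edge, i.e. the
#'   variance ratio is effectively 0 or infinite), U (eigenvectors),
#'   d (eigenvalues).
#' @export
emma_reml <- function(y, X, K, log_delta_range = c(-10, 10),
                      n_grid = 101) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, n >= ncol(X) + 2)
  ek <- eigen(K, symmetric = TRUE)
  if (min(ek$values) < -1e-6 * max(abs(ek$values))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  d <- pmax(ek$values, 0)
  U <- ek$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  logdet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  grid <- seq(log_delta_range[1], log_delta_range[2], length.out = n_grid)
  ll <- vapply(grid, emma_restricted_ll, 0, yt = yt, Xt = Xt, d = d,
               logdet_xx = logdet_xx)
  i <- which.max(ll)
  boundary <- i == 1 || i == n_grid
  if (boundary) {
    warning("REML optimum at the delta grid boundary: variance ratio ",
            "effectively 0 or infinite", call. = FALSE)
    best_ld <- grid[i]
    best_ll <- ll[i]
  } else {
    opt <- stats::optimize(emma_restricted_ll, grid[c(i - 1, i + 1)],
                           maximum = TRUE, yt = yt, Xt = Xt, d = d,
                           logdet_xx = logdet_xx)
    best_ld <- opt$maximum
    best_ll <- opt$objective
  }
  delta <- exp(best_ld)
  w <- d + delta
  Xw <- Xt / sqrt(w); yw <- yt / sqrt(w)
  beta <- solve(crossprod(Xw), crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% beta)^2)
  s2g <- rss / (n - ncol(X))
  out <- list(sigma2_g = s2g, sigma2_e = s2g * delta, delta = delta,
              loglik = as.numeric(best_ll), boundary = boundary,
              U = U, d = d)
  class(out) <- "emma_fit"
  out
}

#' Mixed-model association scan with Q+K genomic control
#'
#' Per marker, a generalized-least-squares t-test of the SNP dosage
#' coefficient (coded 0/1/2, heterozygote 1, missing imputed to the
#' mean dosage) in the model y = intercept + Q + SNP + u + e, after
#' rotating by the kinship eigenvectors.  The Q matrix is reduced to
#' K - 1 columns (the last is dropped; rows sum to one, so the full
#' matrix is collinear with the intercept).  With `p3d = TRUE`
#' (default) the null-model variance components are reused for every
#' marker; `p3d = FALSE` re-estimates them per marker.
#'
#' @param trait named per-accession trait vector.
#' @param genotypes accession x marker call matrix.
#' @param Q optional admixture matrix (accessions x K).
#' @param kinship kinship matrix; computed by [vanraden_kinship()] from
#'   `genotypes` when NULL.
#' @param p3d reuse null variance components across markers.
#' @return data.frame: marker, mm_beta, mm_se, mm_t, mm_p, skipped,
#'   reason; attributes `vc` (null-model emma fit) and `df`.
#' @export
mm_scan <- function(trait, genotypes, Q = NULL, kinship = NULL,
                    p3d = TRUE) {
  stopifnot(!is.null(names(trait)),
            all(names(trait) %in% rownames(genotypes)))
  acc <- names(trait)
  G <- geno_codes(genotypes[acc, , drop = FALSE])
  y <- as.numeric(trait)
  n <- length(y)
  if (is.null(kinship)) kinship <- vanraden_kinship(genotypes[acc, , drop = FALSE])
  K <- if (is.null(rownames(kinship))) kinship else kinship[acc, acc]

  X0 <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)[acc, , drop = FALSE]
    if (ncol(Qm) > 1) {
      X0 <- cbind(X0, Qm[, -ncol(Qm), drop = FALSE])
    }
  }

  null_fit <- emma_reml(y, X0, K)
  U <- null_fit$U; d <- null_fit$d

  # impute missing dosages to the marker mean
  p_mk <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) {
    G[is.na(G[, j]), j] <- p_mk[j]
  }
  mono <- apply(G, 2, stats::var) == 0 | is.na(p_mk)

  scan_once <- function(delta) {
    w <- d + delta
    sw <- sqrt(w)
    yw <- crossprod(U, y) / sw
    Cw <- crossprod(U, X0) / sw
    Gw <- crossprod(U, G) / sw
    qrC <- qr(Cw)
    yr <- qr.resid(qrC, yw)
    Gr <- qr.resid(qrC, Gw)
    den <- colSums(Gr^2)
    beta <- colSums(Gr * as.vector(yr)) / den
    rss0 <- sum(yr^2)
    rss <- rss0 - beta^2 * den
    df <- n - ncol(X0) - 1
    s2 <- rss / df
    se <- sqrt(s2 / den)
    tt <- beta / se
    list(beta = beta, se = se, t = tt,
         p = 2 * stats::pt(-abs(tt), df), den = den, df = df)
  }

  if (p3d) {
    sc <- scan_once(null_fit$delta)
    beta <- sc$beta; se <- sc$se; tt <- sc$t; pp <- sc$p
    den <- sc$den; df <- sc$df
  } else {
    m <- ncol(G)
    beta <- se <- tt <- pp <- den <- rep(NA_real_, m)
    df <- n - ncol(X0) - 1
    for (j in seq_len(m)) {
      if (mono[j]) next
      Xj <- cbind(X0, snp = G[, j])
      fitj <- suppressWarnings(emma_reml(y, Xj, K))
      w <- d + fitj$delta
      sw <- sqrt(w)
      yw <- crossprod(U, y) / sw
      Cw <- crossprod(U, X0) / sw
      gw <- crossprod(U, G[, j]) / sw
      qrC <- qr(Cw)
      yr <- qr.resid(qrC, yw)
      gr <- qr.resid(qrC, gw)
      den[j] <- sum(gr^2)
      beta[j] <- sum(gr * yr) / den[j]
      rss <- sum(yr^2) - beta[j]^2 * den[j]
      se[j] <- sqrt((rss / df) / den[j])
      tt[j] <- beta[j] / se[j]
      pp[j] <- 2 * stats::pt(-abs(tt[j]), df)
    }
  }

  collinear <- den < 1e-10 * n
  out <- data.frame(marker = colnames(G),
                    mm_beta = ifelse(mono | collinear, NA_real_, beta),
                    mm_se = ifelse(mono | collinear, NA_real_, se),
                    mm_t = ifelse(mono | collinear, NA_real_, tt),
                    mm_p = ifelse(mono | collinear, NA_real_, pp),
                    skipped = mono | collinear,
                    reason = ifelse(mono, "monomorphic",
                                    ifelse(collinear, "collinear with covariates",
                                           NA_character_)),
                    row.names = NULL)
  attr(out, "vc") <- null_fit
  attr(out, "df") <- df
  out
}

#' Run both association tests for one trait
#'
#' @param trait named per-accession trait vector.
#' @param genotypes accession x marker call matrix.
#' @param Q optional admixture covariates.
#' @param kinship optional kinship matrix.
#' @param kw_alpha,mm_alpha significance thresholds for the two tests
#'   (defaults 0.005 and 0.01).
#' @param ... passed to [mm_scan()].
#' @return merged association records: marker, kw/mm statistics,
#'   passes_kw (kw_p <= kw_alpha), passes_mm (mm_p <= mm_alpha),
#'   passes_both.
#' @export
assoc_scan <- function(trait, genotypes, Q = NULL, kinship = NULL,
                       kw_alpha = 0.005, mm_alpha = 0.01, ...) {
  kw <- kw_scan(trait, genotypes)
  mm <- mm_scan(trait, genotypes, Q = Q, kinship = kinship, ...)
  rec <- merge(kw[c("marker", "n_AA", "n_BB", "kw_H", "kw_p")],
               mm[c("marker", "mm_beta", "mm_se", "mm_t", "mm_p")],
               by = "marker", sort = FALSE)
  rec$passes_kw <- !is.na(rec$kw_p) & rec$kw_p <= kw_alpha
  rec$passes_mm <- !is.na(rec$mm_p) & rec$mm_p <= mm_alpha
  rec$passes_both <- rec$passes_kw & rec$passes_mm
  rec
}

#' Intersect association hits across traits and build plot tables
#'
#' @param records named list of per-trait association records from
#'   [assoc_scan()].
#' @param map optional marker map for sorting and Manhattan
#'   coordinates.
#' @return list (`assoc_report`): hits (per-trait marker vectors
#'   passing both tests), counts, shared_all (markers hitting every
#'   trait), pairwise_shared, manhattan (long table: trait, marker,
#'   chrom, pos, mm_p, kw_p, neglog10_mm_p), qq (per trait: observed
#'   and expected -log10 p).
#' @export
intersect_and_report <- function(records, map = NULL) {
  stopifnot(is.list(records), length(records) >= 1,
            !is.null(names(records)))
  hits <- lapply(records, function(r) r$marker[r$passes_both])
  counts <- vapply(hits, length, 0L)
  shared_all <- Reduce(intersect, hits)
  traits <- names(records)
  pairwise <- list()
  if (length(traits) >= 2) {
    cmb <- utils::combn(traits, 2)
    for (i in seq_len(ncol(cmb))) {
      key <- paste(cmb[, i], collapse = ":")
      pairwise[[key]] <- intersect(hits[[cmb[1, i]]], hits[[cmb[2, i]]])
    }
  }
  manhattan <- do.call(rbind, lapply(traits, function(tr) {
    r <- records[[tr]]
    out <- data.frame(trait = tr, marker = r$marker,
                      kw_p = r$kw_p, mm_p = r$mm_p,
                      neglog10_mm_p = -log10(r$mm_p))
    if (!is.null(map)) {
      idx <- match(out$marker, map$marker)
      out$chrom <- map$chrom[idx]
      out$pos <- map$pos[idx]
      out <- out[order(out$chrom, out$pos), ]
    }
    out
  }))
  rownames(manhattan) <- NULL
  qq <- do.call(rbind, lapply(traits, function(tr) {
    p <- sort(records[[tr]]$mm_p[!is.na(records[[tr]]$mm_p)])
    if (!length(p)) return(NULL)
    data.frame(trait = tr,
               observed = -log10(p),
               expected = -log10((seq_along(p) - 0.5) / length(p)))
  }))
  out <- list(hits = hits, counts = counts, shared_all = shared_all,
              pairwise_shared = pairwise, manhattan = manhattan, qq = qq)
  class(out) <- "assoc_report"
  out
}

#' Genomic inflation factor
#'
#' lambda = median observed chi-square (from two-sided p-values) over
#' the median of chi-square with 1 df.
#'
#' @param p vector of p-values.
#' @return lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
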
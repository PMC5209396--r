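# Independent oracles used to cross-check the package implementations.

# Full dynamic-programming Smith-Waterman score with affine gaps
# (a gap of length L costs open + ext * L), plain R, O(nm).
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- Ex <- Fy <- matrix(0, n + 1, m + 1)
  Ex[] <- Fy[] <- -Inf
  top <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      Ex[i, j] <- max(Ex[i, j - 1] - ext, best[i, j - 1] - open - ext)
      Fy[i, j] <- max(Fy[i - 1, j] - ext, best[i - 1, j] - open - ext)
      best[i, j] <- max(0, best[i - 1, j - 1] + s, Ex[i, j], Fy[i, j])
      if (best[i, j] > top) top <- best[i, j]
    }
  }
  top
}

# Exhaustive two-group rank-sum permutation p-value: probability (over
# all assignments of the observed values to groups of the observed
# sizes) of a tie-corrected H at least as large as observed.
kw_perm_oracle <- function(y, g) {
  H_of <- function(y, g) {
    N <- length(y)
    r <- rank(y)
    Rsum <- tapply(r, g, sum)
    nn <- tapply(r, g, length)
    H <- 12 / (N * (N + 1)) * sum(Rsum^2 / nn) - 3 * (N + 1)
    tie <- table(y)
    corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
    if (corr == 0) 0 else H / corr
  }
  h_obs <- H_of(y, g)
  n1 <- sum(g == unique(g)[1])
  idx <- utils::combn(length(y), n1)
  h_all <- apply(idx, 2, function(i) {
    gg <- rep(2, length(y)); gg[i] <- 1
    H_of(y, gg)
  })
  mean(h_all >= h_obs - 1e-9)
}

# Spreadsheet-style Evanno arithmetic on a runs x K log-likelihood
# matrix (column names = K values).
evanno_oracle <- function(mat) {
  Ks <- as.numeric(colnames(mat))
  L <- colMeans(mat)
  S <- apply(mat, 2, stats::sd)
  out <- data.frame(K = Ks, deltaK = NA_real_)
  for (i in seq_along(Ks)) {
    if (i == 1 || i == length(Ks)) next
    lp_next <- L[i + 1] - L[i]
    lp_here <- L[i] - L[i - 1]
    out$deltaK[i] <- abs(lp_next - lp_here) / S[i]
  }
  out
}

# small genotype matrix builder: calls from allele-dosage codes
geno_from_codes <- function(codes) {
  calls <- matrix(c("AA", "AB", "BB")[codes + 1],
                  nrow = nrow(codes), dimnames = dimnames(codes))
  calls
}

# balanced one-way ANOVA variance-component estimates (closed form)
anova_vc_oracle <- function(y, g) {
  r <- unname(table(g)[1])
  means <- tapply(y, g, mean)
  msb <- r * stats::var(means)
  mse <- mean(tapply(y, g, stats::var))
  c(line = (msb - mse) / r, resid = mse)
}
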
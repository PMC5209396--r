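# Exact test of Hardy-Weinberg proportions for one biallelic marker,
# by full enumeration of heterozygote counts conditional on the allele
# counts, plus an optional permutation estimator of the same p-value.

#' Enumerate the conditional distribution of heterozygote counts
#'
#' Given nA copies of allele A and na of allele a among N = (nA+na)/2
#' diploids, the probability of observing n_AB heterozygotes is
#' P(n_AB | nA, N) = N! / (n_AA! n_AB! n_aa!) * 2^n_AB * nA! na! / (2N)!
#' over all n_AB with the parity of nA.
#'
#' @param n_a,n_b allele counts (non-negative integers, even total).
#' @return data.frame: n_AB, prob (sums to 1 over the support).
#' @export
hwe_enumerate <- function(n_a, n_b) {
  stopifnot(n_a >= 0, n_b >= 0, (n_a + n_b) %% 2 == 0)
  N <- (n_a + n_b) / 2
  n_ab <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  log_p <- lgamma(N + 1) -
    lgamma((n_a - n_ab) / 2 + 1) - lgamma(n_ab + 1) -
    lgamma((n_b - n_ab) / 2 + 1) +
    n_ab * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * N + 1)
  data.frame(n_AB = n_ab, prob = exp(log_p))
}

#' Exact (and permutation) test of Hardy-Weinberg proportions
#'
#' The exact p-value sums the conditional probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count.  The permutation estimator shuffles the 2N alleles
#' into N diploids `n_permutations` times and applies the same
#' less-or-equally-probable criterion; it converges to the exact
#' p-value as the number of permutations grows.
#'
#' @param n_AA,n_AB,n_BB observed genotype counts.
#' @param n_permutations permutations for the Monte Carlo estimator
#'   (default 10000; 0 skips it).
#' @param seed optional RNG seed for the permutations.
#' @return list (`hwe_result`): n_AA, n_AB, n_BB, p_exact, p_perm
#'   (NA when not requested), n_permutations, support (the enumerated
#'   distribution).  Monomorphic markers return p = 1 by convention.
#' @export
hwe_exact <- function(n_AA, n_AB, n_BB, n_permutations = 10000,
                      seed = NULL) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0, n_AA + n_AB + n_BB >= 1)
  n_a <- 2 * n_AA + n_AB
  n_b <- 2 * n_BB + n_AB
  out <- list(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
              p_exact = 1, p_perm = NA_real_,
              n_permutations = n_permutations, support = NULL)
  class(out) <- "hwe_result"
  if (n_a == 0 || n_b == 0) {           # monomorphic
    if (n_permutations > 0) out$p_perm <- 1
    return(out)
  }
  supp <- hwe_enumerate(n_a, n_b)
  out$support <- supp
  p_obs <- supp$prob[supp$n_AB == n_AB]
  out$p_exact <- min(1, sum(supp$prob[supp$prob <= p_obs * (1 + 1e-9)]))

  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    N <- (n_a + n_b) / 2
    alleles <- rep(c(1L, 0L), c(n_a, n_b))
    extreme <- 0L
    prob_of <- stats::setNames(supp$prob, supp$n_AB)
    for (i in seq_len(n_permutations)) {
      s <- sample(alleles)
      h <- sum(s[seq(1, 2 * N, 2)] != s[seq(2, 2 * N, 2)])
      if (prob_of[[as.character(h)]] <= p_obs * (1 + 1e-9)) {
        extreme <- extreme + 1L
      }
    }
    # add-one estimator keeps the estimate inside (0, 1]
    out$p_perm <- (extreme + 1) / (n_permutations + 1)
  }
  out
}

#' HWE exact test across all markers of a genotype matrix
#'
#' @param genotypes accession x marker call matrix.
#' @param n_permutations permutations per marker (default 0: exact
#'   enumeration only, which the permutation estimator approximates).
#' @param seed optional RNG seed.
#' @return data.frame: marker, n_AA, n_AB, n_BB, p_exact, p_perm.
#' @export
hwe_scan <- function(genotypes, n_permutations = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    if (sum(!is.na(g) & g %in% GENO_CALLS) == 0) {
      return(data.frame(marker = colnames(genotypes)[j],
                        n_AA = 0L, n_AB = 0L, n_BB = 0L,
                        p_exact = NA_real_, p_perm = NA_real_))
    }
    r <- hwe_exact(sum(g == "AA", na.rm = TRUE),
                   sum(g == "AB", na.rm = TRUE),
                   sum(g == "BB", na.rm = TRUE),
                   n_permutations = n_permutations)
    data.frame(marker = colnames(genotypes)[j],
               n_AA = r$n_AA, n_AB = r$n_AB, n_BB = r$n_BB,
               p_exact = r$p_exact, p_perm = r$p_perm)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
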
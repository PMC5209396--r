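# Synthetic genotyped diversity panel with known admixture structure.
# Subpopulation allele frequencies follow the Balding-Nichols model:
# given an ancestral frequency p and divergence F, each subpopulation
# draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F).  Individuals
# are admixed (Dirichlet proportions) and essentially fully inbred: one
# allele is drawn per individual and doubled, with a small independent
# probability of a heterozygous call.

#' Configuration for the diversity-panel generator
#'
#' Defaults emulate a 96-accession, ~650-marker highly homozygous
#' diversity set with three admixed subpopulations (mean heterozygous
#' call rate about 2\%).
#'
#' @param n_accessions,n_markers panel dimensions.
#' @param n_subpops number of ancestral subpopulations (>= 1).
#' @param fst Balding-Nichols divergence, in (0, 1).
#' @param admixture_alpha symmetric Dirichlet concentration of the
#'   per-accession admixture proportions (small values give
#'   near-discrete membership).
#' @param het_rate probability that a call is heterozygous.
#' @param missing_rate probability that a call is missing.
#' @param prop_unplaced fraction of markers assigned to the unplaced
#'   pseudo-chromosome "group 10".
#' @param chrom_length_bp length of each placed pseudo-chromosome.
#' @param seed integer RNG seed.
#' @return a `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_accessions = 96, n_markers = 653,
                             n_subpops = 3, fst = 0.25,
                             admixture_alpha = 0.2, het_rate = 0.02,
                             missing_rate = 0.01, prop_unplaced = 0.14,
                             chrom_length_bp = 250e6, seed = 1) {
  stopifnot(n_accessions >= 2, n_markers >= 1, n_subpops >= 1)
  check_fraction(fst, "fst", open = TRUE)
  stopifnot(admixture_alpha > 0)
  check_fraction(het_rate, "het_rate")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(prop_unplaced, "prop_unplaced")
  structure(list(n_accessions = n_accessions, n_markers = n_markers,
                 n_subpops = n_subpops, fst = fst,
                 admixture_alpha = admixture_alpha, het_rate = het_rate,
                 missing_rate = missing_rate, prop_unplaced = prop_unplaced,
                 chrom_length_bp = chrom_length_bp, seed = seed),
            class = "panel_sim_config")
}

#' Simulate a genotyped diversity panel with admixture structure
#'
#' @param config a [panel_sim_config()].
#' @return list with `genotypes` (accessions x markers character matrix
#'   of AA/AB/BB/NA calls), `map` (marker, chrom, pos; chrom 10 =
#'   unplaced), `Q_truth` (accessions x K admixture proportions),
#'   `subpop_freqs` (K x markers allele-B frequencies), `groups`
#'   (accession labels "wild" for subpopulation 1 majority membership,
#'   "crop" otherwise, mirroring a wild/domesticated split), `ancestral_p`
#'   and the `config`.
#' @export
simulate_diversity_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  m <- config$n_markers
  K <- config$n_subpops
  F <- config$fst

  accessions <- sprintf("acc%03d", seq_len(n))
  markers <- sprintf("mk%04d", seq_len(m))

  p_anc <- stats::runif(m, 0.1, 0.9)
  # Balding-Nichols subpopulation frequencies
  subpop_freqs <- matrix(stats::rbeta(K * m,
                                      shape1 = rep(p_anc * (1 - F) / F, each = K),
                                      shape2 = rep((1 - p_anc) * (1 - F) / F, each = K)),
                         nrow = K, dimnames = list(NULL, markers))

  Q <- rdirichlet(n, rep(config$admixture_alpha, K))
  rownames(Q) <- accessions

  # individual allele frequency and a single doubled allele draw
  pi_mat <- clamp(Q %*% subpop_freqs, 1e-9, 1 - 1e-9)  # n x m, freq of allele B
  b <- matrix(stats::rbinom(n * m, 1, pi_mat), nrow = n)
  calls <- ifelse(b == 1, "BB", "AA")
  het <- matrix(stats::runif(n * m) < config$het_rate, nrow = n)
  calls[het] <- "AB"
  miss <- matrix(stats::runif(n * m) < config$missing_rate, nrow = n)
  calls[miss] <- NA_character_
  dimnames(calls) <- list(accessions, markers)

  # physical map: chrom 1-9 placed, chrom 10 = unplaced group
  n_unplaced <- round(config$prop_unplaced * m)
  chrom <- c(sample(1:9, m - n_unplaced, replace = TRUE),
             rep(10L, n_unplaced))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    L <- if (ch == 10) 50e6 else config$chrom_length_bp
    pos[idx] <- sort(sample.int(L, length(idx)))
  }
  map <- data.frame(marker = markers, chrom = as.integer(chrom), pos = pos)

  groups <- stats::setNames(
    ifelse(max.col(Q) == 1, "wild", "crop"), accessions)

  list(genotypes = calls, map = map, Q_truth = Q,
       subpop_freqs = subpop_freqs, ancestral_p = p_anc,
       groups = groups, config = config)
}
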
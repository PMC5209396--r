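# Synthetic aphid-count trial.  Counts are generated from a latent
# Gaussian variable on the square-root scale, so that the
# sqrt(x + 0.375) transform used in the analysis is variance-stabilizing
# by construction and REML variance components are recoverable:
#   t = mu + QTL effects + line (polygenic) + replicate + block + e
#   total count = round(max(0, t^2 - 0.375))
#   alates ~ Binomial(total, alate fraction)

#' Configuration for the aphid-trial generator
#'
#' Defaults emulate a 96-line alpha-design screen with ten replicates of
#' 8 blocks x 12 pots and a grand mean total count calibrated to about
#' 132 aphids per plant.
#'
#' @param n_lines,n_replicates,blocks_per_replicate,pots_per_block trial
#'   geometry (see [generate_alpha_design()]).
#' @param qtl_markers data.frame (`marker`, `effect`) of planted
#'   marker-linked resistance effects on the square-root scale; the
#'   difference between opposite homozygotes equals `effect` (an AB call
#'   sits halfway).  `NULL` for none.
#' @param polygenic_var variance of the latent line effect (sqrt scale);
#'   with a kinship matrix supplied to [simulate_aphid_trial()] the line
#'   effects are correlated accordingly, otherwise i.i.d.
#' @param rep_var,block_var,resid_var variances of replicate, block
#'   (nested in replicate) and residual effects on the sqrt scale.
#' @param alate_fraction_mean expected fraction of alate (winged) morphs.
#' @param mean_total_target target grand mean of the total count; the
#'   latent intercept is solved from it.
#' @param seed integer RNG seed.
#' @return a `trial_sim_config` list.
#' @export
trial_sim_config <- function(n_lines = 96, n_replicates = 10,
                             blocks_per_replicate = 8, pots_per_block = 12,
                             qtl_markers = NULL, polygenic_var = 3,
                             rep_var = 0.2, block_var = 0.3,
                             resid_var = 1.5, alate_fraction_mean = 0.22,
                             mean_total_target = 132.327, seed = 1) {
  stopifnot(polygenic_var >= 0, rep_var >= 0, block_var >= 0, resid_var >= 0)
  check_fraction(alate_fraction_mean, "alate_fraction_mean")
  if (!is.null(qtl_markers)) {
    stopifnot(is.data.frame(qtl_markers),
              all(c("marker", "effect") %in% names(qtl_markers)))
  }
  structure(list(n_lines = n_lines, n_replicates = n_replicates,
                 blocks_per_replicate = blocks_per_replicate,
                 pots_per_block = pots_per_block, qtl_markers = qtl_markers,
                 polygenic_var = polygenic_var, rep_var = rep_var,
                 block_var = block_var, resid_var = resid_var,
                 alate_fraction_mean = alate_fraction_mean,
                 mean_total_target = mean_total_target, seed = seed),
            class = "trial_sim_config")
}

#' Simulate an alpha-design aphid-count trial
#'
#' @param design a design from [generate_alpha_design()] (or any
#'   data.frame with plant_id, replicate, block, pot, line).
#' @param config a [trial_sim_config()].
#' @param genotypes accession x marker call matrix; required when
#'   `config$qtl_markers` is non-NULL.  Line names of the design must
#'   match its rownames.
#' @param kinship optional PSD matrix correlating the latent line
#'   effects (rows/cols = lines); identity when omitted.
#' @return the design data.frame extended with `alate`, `apterous`,
#'   `total` counts.  Attributes: `truth` (list with line effects, the
#'   variance components used, and the plot-basis broad-sense
#'   heritability implied by the config) and `config`.
#' @export
simulate_aphid_trial <- function(design, config = trial_sim_config(),
                                 genotypes = NULL, kinship = NULL) {
  stopifnot(inherits(config, "trial_sim_config"),
            all(c("plant_id", "replicate", "block", "pot", "line") %in%
                  names(design)))
  set.seed(config$seed)
  lines <- sort(unique(design$line))
  n_lines <- length(lines)

  # marker-linked (QTL) shifts per line on the sqrt scale
  qtl_shift <- stats::setNames(numeric(n_lines), lines)
  if (!is.null(config$qtl_markers)) {
    if (is.null(genotypes)) {
      stop("`genotypes` must be supplied when qtl_markers are planted",
           call. = FALSE)
    }
    missing_mk <- setdiff(config$qtl_markers$marker, colnames(genotypes))
    if (length(missing_mk)) {
      stop("unknown QTL marker id(s): ", paste(missing_mk, collapse = ", "),
           call. = FALSE)
    }
    if (!all(lines %in% rownames(genotypes))) {
      stop("design lines missing from the genotype matrix", call. = FALSE)
    }
    for (i in seq_len(nrow(config$qtl_markers))) {
      mk <- config$qtl_markers$marker[i]
      eff <- config$qtl_markers$effect[i]
      code <- geno_codes(genotypes[lines, mk])
      code[is.na(code)] <- mean(code, na.rm = TRUE)
      qtl_shift <- qtl_shift + eff * (code - 1) / 2
    }
  }

  # latent effects
  if (config$polygenic_var > 0) {
    if (is.null(kinship)) {
      u <- stats::rnorm(n_lines, 0, sqrt(config$polygenic_var))
    } else {
      Kl <- kinship[lines, lines]
      ek <- eigen(Kl, symmetric = TRUE)
      L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), n_lines)
      u <- as.numeric(L %*% stats::rnorm(n_lines)) * sqrt(config$polygenic_var)
    }
  } else {
    u <- numeric(n_lines)
  }
  names(u) <- lines

  reps <- sort(unique(design$replicate))
  rep_eff <- stats::setNames(stats::rnorm(length(reps), 0, sqrt(config$rep_var)),
                             reps)
  blk_key <- interaction(design$replicate, design$block, drop = TRUE)
  blks <- levels(blk_key)
  blk_eff <- stats::setNames(stats::rnorm(length(blks), 0, sqrt(config$block_var)),
                             blks)

  var_sum <- config$polygenic_var + config$rep_var + config$block_var +
    config$resid_var
  mu <- sqrt(max(config$mean_total_target + 0.375 - var_sum, 0.375)) -
    mean(qtl_shift[design$line])

  t_latent <- mu + qtl_shift[design$line] + u[design$line] +
    rep_eff[as.character(design$replicate)] + blk_eff[as.character(blk_key)] +
    stats::rnorm(nrow(design), 0, sqrt(config$resid_var))

  total <- as.integer(round(pmax(0, t_latent^2 - 0.375)))
  alate <- stats::rbinom(length(total), total, config$alate_fraction_mean)

  trial <- design
  trial$alate <- alate
  trial$apterous <- total - alate
  trial$total <- total
  class(trial) <- "data.frame"
  attr(trial, "truth") <- list(
    mu = mu, line_effects = u, qtl_shift = qtl_shift,
    rep_effects = rep_eff, block_effects = blk_eff,
    variance_components = c(line = config$polygenic_var,
                            replicate = config$rep_var,
                            block = config$block_var,
                            resid = config$resid_var),
    h2_plot = if (var_sum > 0) config$polygenic_var / var_sum else NA_real_)
  attr(trial, "config") <- config
  trial
}
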
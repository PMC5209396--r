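# Population-structure layer: maximum-likelihood admixture proportions
# via an alternating EM under a binomial (independent allele frequency)
# likelihood, replicate log-likelihoods across K, Evanno delta-K model
# choice, and genotype PCA.
#
# This is deliberately not a Bayesian MCMC with correlated allele
# frequencies: the EM produces the two artefacts the downstream
# pipeline consumes - per-accession Q covariates and per-K
# log-likelihoods - with a monotone, testable update.

#' Maximum-likelihood admixture estimation by EM
#'
#' Model: the two alleles of accession i at marker j are independent
#' draws with P(allele B) = sum_k q_ik f_kj.  The EM alternates
#' closed-form updates of the admixture rows (q_i, summing to 1) and
#' the subpopulation allele-frequency columns (f_kj); the observed-data
#' binomial log-likelihood is non-decreasing at every iteration (this
#' is asserted).  Missing genotypes contribute no likelihood terms.
#'
#' @param genotypes accession x marker matrix: numeric 0/1/2 allele-B
#'   dosages or AA/AB/BB calls; NA allowed.
#' @param K number of subpopulations (>= 1; K = 1 is closed-form).
#' @param n_restarts random restarts; the best log-likelihood wins.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood
#'   change).
#' @param seed optional RNG seed for the restarts.
#' @return list (`admixture_fit`): Q (n x K, rows sum to 1), F (K x m
#'   allele-B frequencies), loglik, n_iter, converged (FALSE when
#'   max_iter was hit, with a warning), K, restart_logliks.
#' @export
admixture_em <- function(genotypes, K, n_restarts = 1, max_iter = 500,
                         tol = 1e-4, seed = NULL) {
  stopifnot(K >= 1)
  if (!is.null(seed)) set.seed(seed)
  G <- if (is.character(genotypes)) geno_codes(genotypes) else genotypes
  stopifnot(is.matrix(G))
  n <- nrow(G); m <- ncol(G)
  obs <- !is.na(G)
  Gm <- ifelse(obs, G, 0)            # allele-B counts, zeroed when missing
  Hm <- ifelse(obs, 2 - G, 0)        # allele-A counts
  m_i <- pmax(2 * rowSums(obs), 1)   # alleles observed per accession
  const <- sum(lchoose(2, G[obs]))   # binomial coefficient term

  loglik_of <- function(P) {
    const + sum(Gm * log(P) + Hm * log1p(-P))
  }

  if (K == 1) {                       # closed form: observed frequencies
    f <- colSums(Gm) / pmax(colSums(2 * obs), 1)
    f <- clamp(f, 1e-9, 1 - 1e-9)
    P <- matrix(f, n, m, byrow = TRUE)
    out <- list(Q = matrix(1, n, 1, dimnames = list(rownames(G), NULL)),
                F = matrix(f, 1, m, dimnames = list(NULL, colnames(G))),
                loglik = loglik_of(P), n_iter = 0L, converged = TRUE,
                K = 1L, restart_logliks = NA_real_)
    class(out) <- "admixture_fit"
    return(out)
  }

  p_obs <- colSums(Gm) / pmax(colSums(2 * obs), 1)
  best <- NULL
  restart_ll <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    Q <- rdirichlet(n, rep(1, K))
    F <- clamp(matrix(rep(p_obs, each = K), K, m) +
                 matrix(stats::runif(K * m, -0.2, 0.2), K, m), 0.02, 0.98)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      P <- clamp(Q %*% F, 1e-12, 1 - 1e-12)
      A_q <- matrix(0, n, K)           # expected allele counts by origin k
      A_f_num <- matrix(0, K, m)
      A_f_den <- matrix(0, K, m)
      for (k in seq_len(K)) {
        wb <- outer(Q[, k], F[k, ]) / P          # P(origin k | allele B)
        wa <- outer(Q[, k], 1 - F[k, ]) / (1 - P)
        ak <- Gm * wb
        bk <- Hm * wa
        A_q[, k] <- rowSums(ak + bk)
        A_f_num[k, ] <- colSums(ak)
        A_f_den[k, ] <- colSums(ak + bk)
      }
      Q <- A_q / m_i
      Q <- Q / rowSums(Q)              # guard against rounding drift
      F <- clamp(A_f_num / pmax(A_f_den, 1e-12), 1e-9, 1 - 1e-9)
      ll <- loglik_of(clamp(Q %*% F, 1e-12, 1 - 1e-12))
      if (ll < ll_prev - 1e-6 * (abs(ll_prev) + 1)) {
        stop("internal error: EM log-likelihood decreased", call. = FALSE)
      }
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
    }
    restart_ll[r] <- ll_prev
    if (is.null(best) || ll_prev > best$loglik) {
      best <- list(Q = Q, F = F, loglik = ll_prev, n_iter = it,
                   converged = converged)
    }
  }
  if (!best$converged) {
    warning("EM did not converge within max_iter", call. = FALSE)
  }
  dimnames(best$Q) <- list(rownames(G), NULL)
  dimnames(best$F) <- list(NULL, colnames(G))
  out <- c(best, list(K = as.integer(K), restart_logliks = restart_ll))
  class(out) <- "admixture_fit"
  out
}

#' Fit the admixture model over a range of K with independent runs
#'
#' Each run is an independently initialized EM fit (no best-of
#' selection within a run), so the run-to-run spread of log-likelihoods
#' per K feeds the Evanno delta-K statistic.
#'
#' @param genotypes accession x marker genotype matrix (calls or
#'   dosages).
#' @param K_range values of K to fit (default 1:6).
#' @param n_runs independent runs per K (default 4).
#' @param seed integer seed; run seeds are derived from it.
#' @param ... passed to [admixture_em()].
#' @return list (`structure_fit`): runs (data.frame K, run, loglik,
#'   converged), Q (best-run Q matrix per K, named list), fits (best
#'   fit per K).
#' @export
fit_structure <- function(genotypes, K_range = 1:6, n_runs = 4, seed = 1,
                          ...) {
  stopifnot(all(K_range >= 1), n_runs >= 1)
  runs <- list()
  Qs <- list()
  fits <- list()
  for (K in K_range) {
    best <- NULL
    for (r in seq_len(n_runs)) {
      fit <- admixture_em(genotypes, K = K, n_restarts = 1,
                          seed = (seed * 997L + K * 101L + r) %% .Machine$integer.max,
                          ...)
      runs[[length(runs) + 1]] <- data.frame(
        K = K, run = r, loglik = fit$loglik, converged = fit$converged)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    Qs[[as.character(K)]] <- best$Q
    fits[[as.character(K)]] <- best
  }
  out <- list(runs = do.call(rbind, runs), Q = Qs, fits = fits)
  class(out) <- "structure_fit"
  out
}

#' Evanno delta-K table from replicate log-likelihoods
#'
#' With L(K) the mean replicate log-likelihood: L'(K) = L(K) - L(K-1),
#' L''(K) = |L'(K+1) - L'(K)|, and delta-K = L''(K) / sd(K).  The
#' absolute value follows Evanno's definition; delta-K is defined for
#' interior K only, and is dropped (with a warning) where the replicate
#' standard deviation is zero.
#'
#' @param runs data.frame with columns `K` and `loglik` (e.g.
#'   `fit_structure(...)$runs`), or a runs x K matrix with K values as
#'   column names.
#' @return data.frame (`evanno_table`): K, n_runs, mean_L, sd_L, Lp,
#'   Lpp, deltaK; attribute `best_K` = interior K maximizing delta-K.
#' @export
evanno_deltaK <- function(runs) {
  if (is.matrix(runs)) {
    runs <- data.frame(K = rep(as.numeric(colnames(runs)),
                               each = nrow(runs)),
                       loglik = as.numeric(runs))
  }
  stopifnot(all(c("K", "loglik") %in% names(runs)))
  Ks <- sort(unique(runs$K))
  if (length(Ks) < 3 || any(diff(Ks) != 1)) {
    stop("need >= 3 consecutive K values for delta-K", call. = FALSE)
  }
  n_runs <- vapply(Ks, function(k) sum(runs$K == k), 0L)
  if (any(n_runs < 2)) {
    stop("need >= 2 runs per K for the replicate standard deviation",
         call. = FALSE)
  }
  mean_L <- vapply(Ks, function(k) mean(runs$loglik[runs$K == k]), 0)
  sd_L <- vapply(Ks, function(k) stats::sd(runs$loglik[runs$K == k]), 0)
  nK <- length(Ks)
  Lp <- c(NA, diff(mean_L))                       # L'(K), K >= 2nd value
  Lpp <- rep(NA_real_, nK)
  Lpp[2:(nK - 1)] <- abs(Lp[3:nK] - Lp[2:(nK - 1)])
  deltaK <- Lpp / sd_L
  if (any(sd_L == 0 & !is.na(Lpp))) {
    warning("delta-K undefined where replicate sd is zero; excluded",
            call. = FALSE)
    deltaK[sd_L == 0] <- NA_real_
  }
  out <- data.frame(K = Ks, n_runs = n_runs, mean_L = mean_L, sd_L = sd_L,
                    Lp = Lp, Lpp = Lpp, deltaK = deltaK)
  best <- if (all(is.na(deltaK))) NA_integer_ else
    Ks[which.max(replace(deltaK, is.na(deltaK), -Inf))]
  attr(out, "best_K") <- best
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Principal component analysis of a genotype matrix
#'
#' Markers are imputed to their mean dosage, centered, and decomposed
#' with `prcomp` (thin SVD).  Eigenvalues are the squared singular
#' values / (n - 1), so they sum to the total centered variance.
#'
#' @param genotypes accession x marker genotype matrix (calls or
#'   dosages).
#' @param n_components components to keep (default all).
#' @return list: scores (accessions x PCs), eigenvalues,
#'   var_explained, rotation.
#' @export
pca_genotypes <- function(genotypes, n_components = NULL) {
  G <- if (is.character(genotypes)) geno_codes(genotypes) else genotypes
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) {
    G[is.na(G[, j]), j] <- mu[j]
  }
  pc <- stats::prcomp(G, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- if (is.null(n_components)) length(ev) else min(n_components, length(ev))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       eigenvalues = ev[seq_len(k)],
       var_explained = ev[seq_len(k)] / sum(ev),
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' @rdname evanno_deltaK
#' @param x,... print method arguments.
#' @method print evanno_table
#' @export
print.evanno_table <- function(x, ...) {
  cat("Evanno delta-K table (best K =", attr(x, "best_K"), ")\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
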
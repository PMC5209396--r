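# Resolvable incomplete-block layout for the insect-count trial.  The
# contractual property is that of an alpha design: any pair of lines
# occurs together in the same block at most twice across the whole
# experiment.  Construction is the classical cyclic one: blocks are
# developed from a generating array over Z_s found by randomized
# search; two lines from different row-groups meet in a replicate
# exactly when the corresponding array entries differ by the right
# residue, so bounding every column-pair difference multiplicity by 2
# bounds the concurrence by 2.  The bound is re-verified on every
# returned design by exhaustive pair enumeration.

# Precomputed 10 x 12 generating array over Z_8 (found once by the
# depth-first search below and verified: every column-pair difference
# multiset has multiplicity <= 2).  It covers the canonical trial
# geometry - up to 10 replicates of 8 blocks x 12 pots - for which the
# stochastic search is expensive; randomization comes from the
# property-preserving symmetries applied in alpha_generating_array().
ALPHA_BASE_10x12_Z8 <- matrix(c(
  0, 7, 7, 3, 1, 3, 3, 6, 5, 6, 2, 6,
  0, 1, 3, 7, 0, 4, 6, 3, 3, 3, 4, 7,
  0, 0, 5, 7, 1, 4, 1, 1, 2, 6, 1, 3,
  0, 3, 4, 5, 6, 1, 2, 2, 3, 0, 5, 6,
  0, 7, 2, 0, 3, 7, 3, 5, 5, 4, 1, 7,
  0, 1, 0, 2, 7, 0, 6, 2, 4, 1, 0, 0,
  0, 3, 1, 6, 4, 5, 1, 5, 4, 3, 4, 4,
  0, 4, 2, 0, 3, 2, 4, 1, 7, 2, 0, 4,
  0, 2, 7, 2, 4, 2, 2, 0, 6, 4, 6, 3,
  0, 6, 0, 1, 6, 3, 0, 3, 6, 7, 5, 0), nrow = 10, byrow = TRUE)

# r x k generating array over Z_s such that for every pair of columns
# each difference mod s occurs at most twice.  Geometries covered by
# the precomputed base array use it after a random property-preserving
# transformation (row/column permutation, unit multiplier, per-row
# additive constants); other geometries are solved by randomized
# depth-first search over the rows of one column at a time,
# backtracking when a partial column exhausts a difference residue
# against any earlier column.
alpha_generating_array <- function(r, k, s, max_tries = 30,
                                   max_nodes = 200000) {
  if (r > 2 * s) {
    stop(sprintf(paste0("concurrence bound violated: %d replicates force ",
                        "some line pair into a shared block more than ",
                        "twice (need replicates <= 2 x %d blocks)"), r, s),
         call. = FALSE)
  }
  if (s == 8 && r <= nrow(ALPHA_BASE_10x12_Z8) &&
      k <= ncol(ALPHA_BASE_10x12_Z8)) {
    base <- ALPHA_BASE_10x12_Z8[sample.int(10)[seq_len(r)],
                                sample.int(12)[seq_len(k)], drop = FALSE]
    u <- sample(c(1L, 3L, 5L, 7L), 1)          # unit of Z_8
    shift <- sample.int(s, r, replace = TRUE) - 1L
    return((u * base + shift) %% s)
  }
  build_col <- function(prev) {
    x <- integer(r)
    cnt <- lapply(prev, function(p) integer(s))
    nodes <- 0L
    dfs <- function(i) {
      if (nodes > max_nodes) return(NULL)
      if (i > r) return(x)
      for (v in sample.int(s) - 1L) {
        ok <- TRUE
        for (cc in seq_along(prev)) {
          d <- (v - prev[[cc]][i]) %% s
          if (cnt[[cc]][d + 1L] >= 2L) { ok <- FALSE; break }
        }
        if (!ok) next
        x[i] <<- v
        for (cc in seq_along(prev)) {
          d <- (v - prev[[cc]][i]) %% s
          cnt[[cc]][d + 1L] <<- cnt[[cc]][d + 1L] + 1L
        }
        nodes <<- nodes + 1L
        res <- dfs(i + 1L)
        if (!is.null(res)) return(res)
        for (cc in seq_along(prev)) {
          d <- (v - prev[[cc]][i]) %% s
          cnt[[cc]][d + 1L] <<- cnt[[cc]][d + 1L] - 1L
        }
      }
      NULL
    }
    dfs(1L)
  }
  for (attempt in seq_len(max_tries)) {
    cols <- list(integer(r))
    ok <- TRUE
    if (k >= 2) {
      for (col in 2:k) {
        nc <- build_col(cols)
        if (is.null(nc)) { ok <- FALSE; break }
        cols[[col]] <- nc
      }
    }
    if (ok) return(do.call(cbind, cols))
  }
  stop("could not find a generating array satisfying the concurrence ",
       "bound; geometry too tight", call. = FALSE)
}

#' Generate an alpha-type resolvable block design
#'
#' Each line appears exactly once per replicate; each replicate is
#' split into `blocks_per_replicate` blocks of at most `pots_per_block`
#' pots, and any pair of lines shares a block at most twice over the
#' whole design.  Lines are randomly assigned to the cells of a cyclic
#' alpha design (surplus cells are left empty when `n_lines` does not
#' fill the geometry, which can only lower concurrence).
#'
#' @param n_lines number of lines; must fit into one replicate.
#' @param n_replicates number of complete replicates; at most
#'   `2 * blocks_per_replicate` (beyond that the concurrence bound is
#'   unattainable for a full geometry).
#' @param blocks_per_replicate,pots_per_block block geometry.
#' @param seed integer RNG seed.
#' @param max_tries randomized search budget for the generating array.
#' @return data.frame (`trial_design`): plant_id, replicate, block,
#'   pot, line.  Block labels are nested within replicate.
#' @export
generate_alpha_design <- function(n_lines, n_replicates,
                                  blocks_per_replicate, pots_per_block,
                                  seed = 1, max_tries = 20000) {
  s <- blocks_per_replicate
  k <- pots_per_block
  capacity <- s * k
  if (n_lines > capacity) {
    stop(sprintf("capacity bound violated: %d lines exceed %d blocks x %d pots",
                 n_lines, s, k), call. = FALSE)
  }
  set.seed(seed)
  lines <- sprintf("line%03d", seq_len(n_lines))

  # k = 1 means singleton blocks: no pair ever shares a block
  a <- if (k >= 2) alpha_generating_array(n_replicates, k, s, max_tries)
       else matrix(0L, n_replicates, k)

  # cells indexed by (row-group l in 0..k-1, residue m in 0..s-1);
  # lines occupy a random subset of cells
  cell_line <- rep(NA_integer_, capacity)
  cell_line[sample.int(capacity, n_lines)] <- sample.int(n_lines)
  cell_of <- function(l, m) l * s + m + 1L

  design <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    do.call(rbind, lapply(seq_len(s), function(j) {
      ln <- stats::na.omit(vapply(seq_len(k) - 1L, function(l) {
        cell_line[cell_of(l, (a[r, l + 1L] + j - 1L) %% s)]
      }, 0L))
      if (length(ln) == 0) return(NULL)
      data.frame(replicate = r, block = j, pot = seq_along(ln),
                 line = lines[ln[sample.int(length(ln))]])
    }))
  }))
  design$plant_id <- sprintf("plant%04d", seq_len(nrow(design)))
  design <- design[c("plant_id", "replicate", "block", "pot", "line")]
  rownames(design) <- NULL
  stopifnot(max(design_concurrence(design)) <= 2L)
  class(design) <- c("trial_design", "data.frame")
  design
}

#' Pairwise block-concurrence counts of a design
#'
#' Brute-force enumeration over all blocks: for every unordered pair of
#' lines, the number of blocks (across all replicates) in which both
#' occur.
#'
#' @param design a design data.frame with `replicate`, `block`, `line`.
#' @return symmetric integer matrix of pair concurrences (diagonal 0).
#' @export
design_concurrence <- function(design) {
  lines <- sort(unique(design$line))
  cnt <- matrix(0L, length(lines), length(lines),
                dimnames = list(lines, lines))
  key <- interaction(design$replicate, design$block, drop = TRUE)
  for (blk in split(design$line, key)) {
    if (length(blk) < 2) next
    idx <- match(blk, lines)
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  diag(cnt) <- 0L
  cnt
}
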
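#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
GENO_CALLS <- c("AA", "AB", "BB")

#' Truncate a percentage to two decimal places
#'
#' Reporting convention used throughout the package: percentages are
#' truncated (not rounded) to two decimals, e.g. 244/653 prints as 37.36.
#'
#' @param x numeric vector of percentages.
#' @return `x` truncated to 2 decimal places.
#' @export
truncate_percent <- function(x) trunc(x * 100) / 100

#' Fold difference between two values
#'
#' @param top,bottom positive numerics; `top/bottom` is reported.
#' @param truncate truncate to an integer fold (default), as used when
#'   quoting "x times more" comparisons between extreme lines.
#' @return fold change, truncated to integer when `truncate = TRUE`.
#' @export
fold_change <- function(top, bottom, truncate = TRUE) {
  stopifnot(is.numeric(top), is.numeric(bottom), all(bottom > 0))
  fc <- top / bottom
  if (truncate) trunc(fc) else fc
}

#' Convert genotype calls to numeric allele-dosage codes
#'
#' Biallelic calls AA/AB/BB become 0/1/2 (count of the B allele);
#' anything else (missing, uncertain) becomes `NA`.
#'
#' @param g character matrix or vector of calls.
#' @return numeric matrix/vector of the same shape.
#' @export
geno_codes <- function(g) {
  codes <- c(AA = 0, AB = 1, BB = 2)
  out <- codes[as.character(g)]
  if (is.matrix(g)) {
    out <- matrix(out, nrow = nrow(g), dimnames = dimnames(g))
  } else {
    names(out) <- names(g)
  }
  unname_ok <- out
  unname_ok
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# substitute a different base at given positions of a base vector
mutate_bases <- function(bases, positions) {
  for (p in positions) {
    bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1)
  }
  bases
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a fraction in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}
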
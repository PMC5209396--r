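# SNP discovery, filtering and ranking between two accession consensus
# sequence sets, reproducing a KASP candidate-panel design:
#   discover  -> positions where unambiguous base calls differ
#   quality   -> drop loci with Phred < 33 in either accession (strict)
#   fragment  -> 150-nt fragment centred on the SNP (74 left / 75 right)
#   unique    -> fragment must align to exactly one reference contig
#                with > 98% identity over >= 90% of its length
#   rank      -> decreasing lower Phred score, top panel_size retained
#   controls  -> swapped-allele duplicate fragments on different contigs

#' Construct a consensus record
#'
#' One accession's consensus call over one reference contig with
#' per-base Phred qualities.
#'
#' @param contig_id reference contig identifier.
#' @param accession accession label.
#' @param bases nucleotide string (may include N for no-calls).
#' @param phred integer vector of per-base Phred scores (0-93), same
#'   length as `bases`.
#' @return a `consensus_record` list.
#' @export
consensus_record <- function(contig_id, accession, bases, phred) {
  bases <- toupper(bases)
  phred <- as.integer(phred)
  if (nchar(bases) != length(phred)) {
    stop("`bases` and `phred` lengths differ", call. = FALSE)
  }
  if (any(phred < 0 | phred > 93)) {
    stop("Phred scores must lie in [0, 93]", call. = FALSE)
  }
  structure(list(contig_id = contig_id, accession = accession,
                 bases = bases, phred = phred),
            class = "consensus_record")
}

#' Compare two consensus records and list candidate SNPs
#'
#' One candidate per position where both accessions have an unambiguous
#' A/C/G/T call and the calls differ; positions with N (or any ambiguity
#' code) in either accession are skipped.
#'
#' @param rec_a,rec_b consensus records for the same contig, equal
#'   length.
#' @return data.frame of candidates: contig_id, position (1-based),
#'   allele_a, allele_b, phred_a, phred_b, min_phred.
#' @export
compare_consensus <- function(rec_a, rec_b) {
  stopifnot(inherits(rec_a, "consensus_record"),
            inherits(rec_b, "consensus_record"))
  if (rec_a$contig_id != rec_b$contig_id) {
    stop("consensus records refer to different contigs", call. = FALSE)
  }
  if (nchar(rec_a$bases) != nchar(rec_b$bases)) {
    stop("consensus pair malformed: sequence lengths differ", call. = FALSE)
  }
  a <- strsplit(rec_a$bases, "")[[1]]
  b <- strsplit(rec_b$bases, "")[[1]]
  ok <- a %in% DNA_BASES & b %in% DNA_BASES & a != b
  pos <- which(ok)
  data.frame(contig_id = rep(rec_a$contig_id, length(pos)), position = pos,
             allele_a = a[pos], allele_b = b[pos],
             phred_a = rec_a$phred[pos], phred_b = rec_b$phred[pos],
             min_phred = pmin(rec_a$phred[pos], rec_b$phred[pos]),
             stringsAsFactors = FALSE)
}

#' Discover candidate SNPs over a full consensus set pair
#'
#' Applies [compare_consensus()] contig by contig.
#'
#' @param consensus_a,consensus_b named lists of consensus records
#'   (keys = contig ids), as produced by [simulate_transcriptome_pair()]
#'   or [read_consensus_fastq()].
#' @return row-bound candidate data.frame with a fresh `status` column
#'   set to "pass".
#' @export
discover_snps <- function(consensus_a, consensus_b) {
  shared <- intersect(names(consensus_a), names(consensus_b))
  out <- do.call(rbind, lapply(shared, function(cid) {
    compare_consensus(consensus_a[[cid]], consensus_b[[cid]])
  }))
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), position = integer(),
                      allele_a = character(), allele_b = character(),
                      phred_a = integer(), phred_b = integer(),
                      min_phred = integer())
  }
  out$status <- rep("pass", nrow(out))
  rownames(out) <- NULL
  out
}

#' Phred quality filter
#'
#' Marks candidates whose lower Phred score falls strictly below the
#' threshold as `low_quality`.  A score exactly at the threshold passes.
#' The pass set is monotone in the threshold.
#'
#' @param candidates candidate data.frame with `min_phred` and `status`.
#' @param threshold minimum acceptable Phred score (default 33).
#' @return candidates with `status` updated.
#' @export
quality_filter <- function(candidates, threshold = 33) {
  fail <- candidates$min_phred < threshold & candidates$status == "pass"
  candidates$status[fail] <- "low_quality"
  candidates
}

#' Extract the 150-nt assay fragment around each candidate
#'
#' The fragment is taken from the accession-A consensus: 74 nt of left
#' flank, the SNP base, and 75 nt of right flank, so the SNP sits at
#' 1-based fragment offset 75.  Candidates within 74 nt of the contig
#' start or 75 nt of the end are marked `edge`.
#'
#' @param candidates candidate data.frame.
#' @param consensus_a named list of accession-A consensus records (or a
#'   named character vector of sequences).
#' @param flank_left,flank_right flank widths (fragment length =
#'   left + 1 + right = 150 by default).
#' @return candidates with `fragment` and updated `status` columns.
#' @export
extract_fragments <- function(candidates, consensus_a,
                              flank_left = 74, flank_right = 75) {
  seqs <- if (is.character(consensus_a)) consensus_a else
    vapply(consensus_a, `[[`, "", "bases")
  frag <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (candidates$status[i] != "pass") next
    s <- seqs[[candidates$contig_id[i]]]
    p <- candidates$position[i]
    start <- p - flank_left
    end <- p + flank_right
    if (start < 1 || end > nchar(s)) {
      candidates$status[i] <- "edge"
    } else {
      frag[i] <- substr(s, start, end)
    }
  }
  candidates$fragment <- frag
  candidates
}

#' Best local alignment identity of a fragment against a subject
#'
#' Smith-Waterman local alignment (via Biostrings) with match +1,
#' mismatch -2 and affine gap cost 5 + 2 per gapped position; both
#' strands are searched and the higher-scoring one reported.  Identity
#' is matches / alignment columns (gaps included); coverage is the
#' aligned fraction of the query.
#'
#' @param query fragment sequence (character).
#' @param subject subject sequence (character), non-empty.
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @param both_strands also align the reverse complement of the query.
#' @return list: identity, score, coverage, strand ("+"/"-"),
#'   subject_start, subject_end.
#' @export
local_align_identity <- function(query, subject, match = 1, mismatch = -2,
                                 gap_opening = 5, gap_extension = 2,
                                 both_strands = TRUE) {
  if (!nzchar(subject)) stop("empty subject sequence", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  align_one <- function(q) {
    Biostrings::pairwiseAlignment(
      pattern = q, subject = subject, type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
  }
  strands <- list(`+` = query)
  if (both_strands) {
    strands$`-` <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(query)))
  }
  best <- NULL
  for (st in names(strands)) {
    al <- align_one(strands[[st]])
    if (is.null(best) || Biostrings::score(al) > best$score) {
      pat <- as.character(Biostrings::alignedPattern(al))
      ncol_aln <- nchar(pat)
      best <- list(
        identity = if (ncol_aln > 0) Biostrings::nmatch(al) / ncol_aln else 0,
        score = Biostrings::score(al),
        coverage = Biostrings::width(Biostrings::pattern(al)) / nchar(query),
        strand = st,
        subject_start = Biostrings::start(Biostrings::subject(al)),
        subject_end = Biostrings::end(Biostrings::subject(al)))
    }
  }
  best
}

#' Uniqueness filter against the reference set
#'
#' A candidate passes only if exactly one reference sequence yields a
#' qualifying hit: local alignment identity strictly greater than
#' `identity_threshold` covering at least `min_coverage` of the 150-nt
#' fragment (both strands searched).  A candidate whose only qualifying
#' hit is its own source contig passes; fragments matching a second
#' contig (e.g. a close paralog) are marked `non_unique`.
#'
#' @param candidates candidate data.frame with `fragment`.
#' @param reference named character vector (or DNAStringSet) of
#'   reference sequences.
#' @param identity_threshold identity cut-off, strict ">" (default 0.98).
#' @param min_coverage minimum fraction of the fragment that a
#'   qualifying hit must span (default 0.90).
#' @return candidates with `status` and `n_hits` updated.
#' @export
uniqueness_filter <- function(candidates, reference,
                              identity_threshold = 0.98,
                              min_coverage = 0.90) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  n_hits <- rep(NA_integer_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (candidates$status[i] != "pass" || is.na(candidates$fragment[i])) next
    frag <- candidates$fragment[i]
    hits <- 0L
    for (cid in names(reference)) {
      al <- local_align_identity(frag, reference[[cid]])
      if (al$identity > identity_threshold && al$coverage >= min_coverage) {
        hits <- hits + 1L
      }
    }
    n_hits[i] <- hits
    if (hits != 1L) candidates$status[i] <- "non_unique"
  }
  candidates$n_hits <- n_hits
  candidates
}

#' Rank passing candidates and select the marker panel
#'
#' Candidates are sorted by decreasing lower Phred score; ties are
#' broken by (contig_id, position) ascending.  The top `panel_size`
#' candidates are retained (all of them, with a warning, if fewer are
#' available).
#'
#' @param candidates candidate data.frame (only rows with status
#'   "pass" are ranked).
#' @param panel_size number of assays to retain (>= 0).
#' @return a `marker_panel` data.frame with `rank` and `marker_id`
#'   columns prepended.
#' @export
rank_and_select <- function(candidates, panel_size) {
  stopifnot(panel_size >= 0)
  pass <- candidates[candidates$status == "pass", , drop = FALSE]
  ord <- order(-pass$min_phred, pass$contig_id, pass$position)
  pass <- pass[ord, , drop = FALSE]
  if (nrow(pass) < panel_size) {
    warning(sprintf("only %d passing candidates available for a panel of %d",
                    nrow(pass), panel_size), call. = FALSE)
  }
  panel <- utils::head(pass, panel_size)
  if (nrow(panel) > 0) {
    panel <- cbind(rank = seq_len(nrow(panel)),
                   marker_id = sprintf("LS1_%d", seq_len(nrow(panel))),
                   panel)
  } else {
    panel <- cbind(rank = integer(0), marker_id = character(0), panel)
  }
  rownames(panel) <- NULL
  panel$control_pair <- rep(NA_character_, nrow(panel))
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Flag internal-control fragment pairs in a panel
#'
#' Internal controls are pairs of panel fragments from different
#' reference contigs whose sequences match (> `identity_threshold`
#' identity) and whose SNP alleles are swapped (one fragment's A allele
#' is the other's B allele and vice versa).  Both members get the same
#' `control_pair` id and count as two markers / one pair in summaries.
#'
#' @param panel a `marker_panel`.
#' @param identity_threshold identity required to call two fragments
#'   the same sequence.
#' @return the panel with `control_pair` filled in.
#' @export
flag_internal_controls <- function(panel, identity_threshold = 0.98) {
  n <- nrow(panel)
  if (n < 2) return(panel)
  pair_id <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (panel$contig_id[i] == panel$contig_id[j]) next
      if (!is.na(panel$control_pair[i]) && !is.na(panel$control_pair[j])) next
      swapped <- panel$allele_a[i] == panel$allele_b[j] &&
        panel$allele_b[i] == panel$allele_a[j]
      if (!swapped) next
      al <- local_align_identity(panel$fragment[i], panel$fragment[j])
      if (al$identity > identity_threshold && al$coverage >= 0.9) {
        pair_id <- pair_id + 1L
        pid <- sprintf("ctrl%02d", pair_id)
        panel$control_pair[c(i, j)] <- pid
      }
    }
  }
  panel
}

#' Design a KASP marker panel from a consensus pair
#'
#' Full discovery-filter-rank chain: discover SNPs, apply the Phred
#' quality filter, extract 150-nt fragments, apply the uniqueness
#' filter against the reference set, rank by decreasing lower Phred and
#' select the panel, then flag internal-control pairs.
#'
#' @param reference named character vector of reference sequences.
#' @param consensus_a,consensus_b consensus record lists for the two
#'   accessions.
#' @param phred_min quality threshold (default 33, strict "<" fails).
#' @param identity_threshold uniqueness identity cut-off (default 0.98).
#' @param panel_size assays to retain (default 682).
#' @return list: `panel` (marker_panel), `candidates` (all candidates
#'   with final status), `summary` (named counts: n_candidates,
#'   n_low_quality, n_edge, n_non_unique, n_pass, n_panel, n_control,
#'   n_noncontrol).
#' @export
design_panel <- function(reference, consensus_a, consensus_b,
                         phred_min = 33, identity_threshold = 0.98,
                         panel_size = 682) {
  cands <- discover_snps(consensus_a, consensus_b)
  cands <- quality_filter(cands, threshold = phred_min)
  cands <- extract_fragments(cands, consensus_a)
  cands <- uniqueness_filter(cands, reference,
                             identity_threshold = identity_threshold)
  panel <- rank_and_select(cands, panel_size)
  panel <- flag_internal_controls(panel, identity_threshold)
  n_control <- sum(!is.na(panel$control_pair))
  summary <- c(n_candidates = nrow(cands),
               n_low_quality = sum(cands$status == "low_quality"),
               n_edge = sum(cands$status == "edge"),
               n_non_unique = sum(cands$status == "non_unique"),
               n_pass = sum(cands$status == "pass"),
               n_panel = nrow(panel),
               n_control = n_control,
               n_control_pairs = n_control %/% 2L,
               n_noncontrol = nrow(panel) - n_control)
  list(panel = panel, candidates = cands, summary = summary)
}
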
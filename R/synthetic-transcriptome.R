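# Synthetic dual-transcriptome generator: a reference EST set plus two
# accession consensus sequence sets that differ at planted SNPs, with
# optional near-identical paralogous contigs and low-quality base calls.
# The planted truth is exhaustive: every SNP the discovery pipeline
# should find (or reject) is recorded.

#' Simulate a reference EST set and a pair of accession consensus sets
#'
#' Accession A's consensus equals the reference; accession B differs at
#' the planted SNP positions only.  A fraction of contigs gets a
#' near-identical paralogous copy (identity >= 98\% by construction)
#' appended to the reference, which the panel uniqueness filter must
#' reject.  Phred qualities default to 40; planted low-quality sites get
#' scores below 33 in both accessions.
#'
#' @param n_contigs number of (non-paralog) reference contigs.
#' @param contig_length contig length(s) in nt, recycled; all must be
#'   >= 150 so a full assay fragment fits.
#' @param snp_rate per-base probability of planting a SNP between the
#'   two accessions.
#' @param paralog_rate fraction of contigs that receive a paralogous
#'   copy.
#' @param low_quality_rate per-base probability of a low-quality call.
#' @param paralog_identity sequence identity of paralog copies (>= 0.98
#'   emulates the confounding case; lower values make paralogs
#'   distinguishable).
#' @param phred_default Phred score of ordinary bases.
#' @param seed integer RNG seed; equal seeds give byte-identical output.
#' @param out_dir optional directory; when given, `reference.fasta`,
#'   `consensus_A.fastq`, `consensus_B.fastq` and `truth_snps.json` are
#'   written there.
#' @return list with `reference` (named character), `consensus_a` /
#'   `consensus_b` (lists of consensus records), `truth` (data.frame of
#'   planted SNPs: contig_id, position, allele_a, allele_b,
#'   low_quality, on_paralog_source), `paralogs` (data.frame contig_id,
#'   paralog_of, identity), `low_quality_sites`, and `files` when
#'   `out_dir` was used.
#' @export
simulate_transcriptome_pair <- function(n_contigs = 10,
                                        contig_length = 1000,
                                        snp_rate = 0.005,
                                        paralog_rate = 0,
                                        low_quality_rate = 0,
                                        paralog_identity = 0.99,
                                        phred_default = 40L,
                                        seed = 1,
                                        out_dir = NULL) {
  check_fraction(snp_rate, "snp_rate")
  check_fraction(paralog_rate, "paralog_rate")
  check_fraction(low_quality_rate, "low_quality_rate")
  lens <- rep_len(as.integer(contig_length), n_contigs)
  if (any(lens < 150)) {
    stop("all contigs must be >= 150 nt: a 150-nt assay fragment cannot ",
         "be hosted by a shorter contig", call. = FALSE)
  }
  set.seed(seed)

  contig_ids <- sprintf("contig%03d", seq_len(n_contigs))
  ref_bases <- lapply(lens, function(L) sample(DNA_BASES, L, replace = TRUE))
  names(ref_bases) <- contig_ids

  # plant SNPs
  truth <- list()
  b_bases <- ref_bases
  for (cid in contig_ids) {
    L <- length(ref_bases[[cid]])
    hit <- which(stats::runif(L) < snp_rate)
    if (length(hit)) {
      alt <- vapply(hit, function(p) {
        sample(setdiff(DNA_BASES, ref_bases[[cid]][p]), 1)
      }, "")
      b_bases[[cid]][hit] <- alt
      truth[[cid]] <- data.frame(
        contig_id = cid, position = hit,
        allele_a = ref_bases[[cid]][hit], allele_b = alt,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig_id = character(), position = integer(),
               allele_a = character(), allele_b = character())
  rownames(truth) <- NULL

  # paralogous copies of a subset of contigs, appended to all three sets
  n_par <- round(paralog_rate * n_contigs)
  paralogs <- data.frame(contig_id = character(), paralog_of = character(),
                         identity = numeric())
  if (n_par > 0) {
    src <- sample(contig_ids, n_par)
    for (cid in src) {
      L <- length(ref_bases[[cid]])
      n_mut <- max(1L, round((1 - paralog_identity) * L))
      pid <- paste0(cid, "_par")
      par_seq <- mutate_bases(ref_bases[[cid]], sample(L, n_mut))
      ref_bases[[pid]] <- par_seq
      b_bases[[pid]] <- par_seq   # paralog carries no accession SNPs
      paralogs <- rbind(paralogs, data.frame(
        contig_id = pid, paralog_of = cid, identity = 1 - n_mut / L))
    }
  }
  truth$on_paralog_source <- truth$contig_id %in% paralogs$paralog_of

  # per-base qualities, shared positions of low-quality calls
  lowq <- lapply(ref_bases, function(b) {
    which(stats::runif(length(b)) < low_quality_rate)
  })
  phred_of <- function(bases, sites) {
    q <- rep(as.integer(phred_default), length(bases))
    if (length(sites)) q[sites] <- sample(15:32, length(sites), replace = TRUE)
    q
  }
  all_ids <- names(ref_bases)
  mk_records <- function(base_list, accession) {
    stats::setNames(lapply(all_ids, function(cid) {
      consensus_record(cid, accession,
                       paste(base_list[[cid]], collapse = ""),
                       phred_of(base_list[[cid]], lowq[[cid]]))
    }), all_ids)
  }
  consensus_a <- mk_records(ref_bases, "A")
  consensus_b <- mk_records(b_bases, "B")
  truth$low_quality <- mapply(function(cid, p) p %in% lowq[[cid]],
                              truth$contig_id, truth$position,
                              USE.NAMES = FALSE)
  if (nrow(truth) == 0) truth$low_quality <- logical(0)

  reference <- vapply(ref_bases, paste, "", collapse = "")
  out <- list(reference = reference, consensus_a = consensus_a,
              consensus_b = consensus_b, truth = truth, paralogs = paralogs,
              low_quality_sites = lowq, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      reference = file.path(out_dir, "reference.fasta"),
      consensus_a = file.path(out_dir, "consensus_A.fastq"),
      consensus_b = file.path(out_dir, "consensus_B.fastq"),
      truth = file.path(out_dir, "truth_snps.json")
    )
    write_reference_fasta(reference, files[["reference"]])
    write_consensus_fastq(consensus_a, files[["consensus_a"]])
    write_consensus_fastq(consensus_b, files[["consensus_b"]])
    jsonlite::write_json(
      list(truth = truth, paralogs = paralogs, seed = seed),
      files[["truth"]], dataframe = "rows", auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
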
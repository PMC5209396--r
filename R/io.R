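# Readers/writers for the plain-text formats the pipeline exchanges.
# Sequences go through Biostrings; tables are plain CSV.

#' Write a reference FASTA file
#'
#' @param reference named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  Biostrings::writeXStringSet(reference, filepath = path)
  invisible(path)
}

#' Read a reference FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write per-accession consensus sequences as FASTQ
#'
#' One FASTQ record per reference contig, Phred+33 qualities.
#'
#' @param records list of consensus records (see [consensus_record()]).
#' @param path output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_consensus_fastq <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "bases"))
  names(seqs) <- vapply(records, `[[`, "", "contig_id")
  quals <- Biostrings::PhredQuality(vapply(records, function(r) {
    as.character(Biostrings::PhredQuality(as.integer(r$phred)))
  }, ""))
  qseqs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qseqs, filepath = path)
  invisible(path)
}

#' Read consensus FASTQ into consensus records
#'
#' @param path FASTQ file (Phred+33).
#' @param accession accession label to attach to each record.
#' @return named list of consensus records, keyed by contig id.
#' @export
read_consensus_fastq <- function(path, accession = NA_character_) {
  q <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  phreds <- methods::as(Biostrings::quality(q), "IntegerList")
  out <- lapply(seq_along(q), function(i) {
    consensus_record(
      contig_id = names(q)[i],
      accession = accession,
      bases = as.character(q[[i]]),
      phred = as.integer(phreds[[i]])
    )
  })
  stats::setNames(out, names(q))
}

#' Write / read the accession-by-marker genotype matrix
#'
#' CSV with accessions as rows, markers as columns, calls AA/AB/BB or NA.
#'
#' @param genotypes character matrix (rows = accessions).
#' @param path CSV file.
#' @return `path` / character matrix.
#' @export
write_genotype_csv <- function(genotypes, path) {
  utils::write.csv(as.data.frame(genotypes, check.names = FALSE), path,
                   row.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        colClasses = "character", na.strings = "NA")
  as.matrix(df)
}

#' Write / read the marker map (marker, chrom, pos)
#'
#' Positions are 1-based bp on pseudo-chromosomes 1-9; markers that could
#' not be placed are conventionally assigned to group 10.
#'
#' @param map data.frame with columns `marker`, `chrom`, `pos`.
#' @param path CSV file.
#' @return `path` / data.frame.
#' @export
write_marker_map_csv <- function(map, path) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map_csv
#' @export
read_marker_map_csv <- function(path) {
  map <- utils::read.csv(path, check.names = FALSE)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.integer(map$pos)
  map
}

#' Write / read the long-format trial table
#'
#' @param trial data.frame with columns `plant_id`, `line`, `replicate`,
#'   `block`, `pot`, `alate`, `apterous`.
#' @param path CSV file.
#' @return `path` / data.frame (with a recomputed `total` column).
#' @export
write_trial_csv <- function(trial, path) {
  cols <- c("plant_id", "line", "replicate", "block", "pot", "alate", "apterous")
  stopifnot(all(cols %in% names(trial)))
  utils::write.csv(trial[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  trial <- utils::read.csv(path, check.names = FALSE)
  trial$total <- trial$alate + trial$apterous
  trial
}

#' Export a genotype matrix as a minimal VCF
#'
#' Diploid GT records (0/0, 0/1, 1/1, ./.) with CHROM/POS taken from
#' the marker map; REF/ALT are written as the generic A/B allele
#' labels.  Markers missing from the map are skipped with a warning.
#'
#' @param genotypes accession x marker call matrix.
#' @param map marker map (marker, chrom, pos).
#' @param path output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, map, path) {
  idx <- match(colnames(genotypes), map$marker)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " marker(s) missing from the map; skipped",
            call. = FALSE)
  }
  keep <- which(!is.na(idx))
  gt_code <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(keep, function(j) {
    calls <- gt_code[genotypes[, j]]
    calls[is.na(calls)] <- "./."
    paste(c(map$chrom[idx[j]], map$pos[idx[j]], colnames(genotypes)[j],
            "A", "B", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  ord <- order(map$chrom[idx[keep]], map$pos[idx[keep]])
  writeLines(c(header, body[ord]), path)
  invisible(path)
}
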
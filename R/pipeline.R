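# End-to-end orchestration on synthetic data: simulate -> panel ->
# popgen -> structure -> phenotype -> assoc, with every stage writing
# plain-text outputs into a run directory and a summary report at the
# end.  All analysis thresholds default to the package's canonical
# values (Phred 33, identity 0.98, het filter 0.20, KW alpha 0.005,
# mixed-model alpha 0.01, 150-nt fragments, sqrt + 0.375 transform).

#' Build a pipeline run configuration
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param out_dir run directory (created if needed).
#' @param stages character subset of
#'   c("simulate","panel","popgen","structure","pheno","assoc").
#' @param phred_min,identity_threshold,panel_size panel-design
#'   thresholds.
#' @param het_max_bad het/uncertain/missing locus filter threshold.
#' @param hwe_permutations permutations for the HWE test (0 = exact
#'   enumeration only).
#' @param K_range,n_runs structure stage settings.
#' @param kw_alpha,mm_alpha association thresholds.
#' @param transcriptome,panel_config,trial_config generator settings:
#'   a list of [simulate_transcriptome_pair()] arguments, a
#'   [panel_sim_config()] and a [trial_sim_config()].
#' @param n_qtl,qtl_effect planted trait QTLs: number of markers and
#'   their effect on the sqrt scale (used when `trial_config` carries
#'   no explicit `qtl_markers`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1,
                       out_dir = file.path(tempdir(), "kaspanel_run"),
                       stages = c("simulate", "panel", "popgen",
                                  "structure", "pheno", "assoc"),
                       phred_min = 33, identity_threshold = 0.98,
                       panel_size = 682, het_max_bad = 0.20,
                       hwe_permutations = 0,
                       K_range = 1:6, n_runs = 4,
                       kw_alpha = 0.005, mm_alpha = 0.01,
                       transcriptome = list(n_contigs = 12,
                                            contig_length = 600,
                                            snp_rate = 0.01,
                                            paralog_rate = 0.15,
                                            low_quality_rate = 0.02),
                       panel_config = panel_sim_config(seed = seed + 1),
                       trial_config = trial_sim_config(seed = seed + 3),
                       n_qtl = 2, qtl_effect = 1.5) {
  stopifnot(all(stages %in% c("simulate", "panel", "popgen", "structure",
                              "pheno", "assoc")))
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 phred_min = phred_min,
                 identity_threshold = identity_threshold,
                 panel_size = panel_size, het_max_bad = het_max_bad,
                 hwe_permutations = hwe_permutations,
                 K_range = K_range, n_runs = n_runs,
                 kw_alpha = kw_alpha, mm_alpha = mm_alpha,
                 transcriptome = transcriptome,
                 panel_config = panel_config,
                 trial_config = trial_config,
                 n_qtl = n_qtl, qtl_effect = qtl_effect),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Stages run in dependency order; every output file lands in
#' `config$out_dir` and the summary (`summary.json`) echoes the seed, a
#' hash of the configuration, the panel size, marker QC counts, the
#' chosen K and the per-trait hit counts.  Rerunning with the same
#' configuration reproduces the summary exactly.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with the in-memory results of each stage plus
#'   `summary` and `out_dir`, invisibly.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  res <- list(out_dir = config$out_dir)

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_json <- config
  cfg_json$out_dir <- NULL        # hash covers the scientific settings only
  cfg_json$panel_config <- unclass(cfg_json$panel_config)
  cfg_json$trial_config <- unclass(cfg_json$trial_config)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  config_hash <- unname(tools::md5sum(cfg_path))

  summary <- list(tool = "kaspanel",
                  version = as.character(utils::packageVersion("kaspanel")),
                  seed = config$seed, config_hash = config_hash)

  # ---- simulate -------------------------------------------------------
  if ("simulate" %in% config$stages) {
    say("stage simulate")
    res$transcriptome <- do.call(simulate_transcriptome_pair,
                                 c(config$transcriptome,
                                   list(seed = config$seed,
                                        out_dir = config$out_dir)))
    res$panel_sim <- simulate_diversity_panel(config$panel_config)
    write_genotype_csv(res$panel_sim$genotypes,
                       file.path(config$out_dir, "genotypes.csv"))
    write_marker_map_csv(res$panel_sim$map,
                         file.path(config$out_dir, "marker_map.csv"))
    utils::write.csv(data.frame(accession = names(res$panel_sim$groups),
                                group = unname(res$panel_sim$groups)),
                     file.path(config$out_dir, "groups.csv"),
                     row.names = FALSE)

    tc <- config$trial_config
    n_lines <- min(tc$n_lines, nrow(res$panel_sim$genotypes))
    res$design <- generate_alpha_design(
      n_lines, tc$n_replicates, tc$blocks_per_replicate,
      tc$pots_per_block, seed = config$seed + 2)
    if (is.null(tc$qtl_markers) && config$n_qtl > 0) {
      af <- allele_frequencies(res$panel_sim$genotypes)
      informative <- af$marker[af$p < 0.8 & !af$all_missing]
      set.seed(config$seed + 4)
      tc$qtl_markers <- data.frame(
        marker = sample(informative, min(config$n_qtl,
                                         length(informative))),
        effect = config$qtl_effect)
    }
    geno_lines <- res$panel_sim$genotypes
    rownames(geno_lines) <- sprintf("line%03d",
                                    seq_len(nrow(geno_lines)))
    res$qtl_truth <- tc$qtl_markers
    res$trial <- simulate_aphid_trial(res$design, tc,
                                      genotypes = geno_lines)
    write_trial_csv(res$trial, file.path(config$out_dir, "trial.csv"))
    jsonlite::write_json(list(qtl_markers = tc$qtl_markers,
                              h2_plot = attr(res$trial, "truth")$h2_plot),
                         file.path(config$out_dir, "truth_trial.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  # ---- panel design ---------------------------------------------------
  if ("panel" %in% config$stages) {
    if (is.null(res$transcriptome)) stop("stage panel needs stage simulate",
                                         call. = FALSE)
    say("stage panel")
    res$panel_design <- design_panel(
      res$transcriptome$reference, res$transcriptome$consensus_a,
      res$transcriptome$consensus_b, phred_min = config$phred_min,
      identity_threshold = config$identity_threshold,
      panel_size = config$panel_size)
    pn <- res$panel_design$panel
    utils::write.table(
      data.frame(rank = pn$rank, marker_id = pn$marker_id,
                 contig = pn$contig_id, pos = pn$position,
                 alleles = paste(pn$allele_a, pn$allele_b, sep = "/"),
                 min_phred = pn$min_phred, status = pn$status,
                 control_pair = pn$control_pair),
      file.path(config$out_dir, "panel.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    summary$panel <- as.list(res$panel_design$summary)
  }

  # ---- popgen ---------------------------------------------------------
  if ("popgen" %in% config$stages) {
    if (is.null(res$panel_sim)) stop("stage popgen needs stage simulate",
                                     call. = FALSE)
    say("stage popgen")
    hf <- het_filter(res$panel_sim$genotypes,
                     max_bad_fraction = config$het_max_bad)
    res$het_filter <- hf
    G <- hf$genotypes
    af <- allele_frequencies(G)
    af$pic <- pic(af$p)
    hwe <- hwe_scan(G, n_permutations = config$hwe_permutations,
                    seed = config$seed + 5)
    stats_tbl <- merge(af, hwe[c("marker", "p_exact", "p_perm")],
                       by = "marker", sort = FALSE)
    utils::write.table(stats_tbl,
                       file.path(config$out_dir, "marker_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ld <- pairwise_ld(G, res$panel_sim$map)
    decay <- ld_decay_table(ld)
    utils::write.table(decay, file.path(config$out_dir, "ld_decay.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    part <- partition_polymorphism(
      G, res$panel_sim$groups[rownames(G)])
    dist <- intermarker_distances(
      res$panel_sim$map[res$panel_sim$map$marker %in% colnames(G), ])
    res$popgen <- list(stats = stats_tbl, ld = ld, decay = decay,
                       partition = part, distances = dist)
    summary$popgen <- list(
      n_loci_kept = ncol(G),
      n_loci_dropped = length(hf$dropped_loci),
      n_monomorphic = part$counts[["monomorphic_overall"]],
      mean_pic = mean(af$pic[af$p < 1], na.rm = TRUE),
      mean_intermarker_bp = dist$mean_bp)
  }

  # ---- structure ------------------------------------------------------
  if ("structure" %in% config$stages) {
    if (is.null(res$het_filter)) stop("stage structure needs stage popgen",
                                      call. = FALSE)
    say("stage structure")
    G <- res$het_filter$genotypes
    sf <- fit_structure(G, K_range = config$K_range,
                        n_runs = config$n_runs, seed = config$seed + 6)
    ev <- evanno_deltaK(sf$runs)
    bestK <- attr(ev, "best_K")
    utils::write.table(sf$runs,
                       file.path(config$out_dir, "structure_runs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(ev),
                       file.path(config$out_dir, "evanno.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    Qb <- sf$Q[[as.character(bestK)]]
    utils::write.csv(as.data.frame(Qb),
                     file.path(config$out_dir,
                               sprintf("qmatrix_K%d.csv", bestK)))
    pca <- pca_genotypes(G)
    res$structure <- list(fit = sf, evanno = ev, best_K = bestK,
                          Q = Qb, pca = pca)
    summary$structure <- list(best_K = bestK,
                              deltaK = max(ev$deltaK, na.rm = TRUE))
  }

  # ---- phenotype ------------------------------------------------------
  if ("pheno" %in% config$stages) {
    if (is.null(res$trial)) stop("stage pheno needs stage simulate",
                                 call. = FALSE)
    say("stage pheno")
    res$pheno <- lapply(c(alate = "alate", apterous = "apterous",
                          total = "total"),
                        function(tr) analyze_trait(res$trial, tr))
    means_out <- do.call(rbind, lapply(names(res$pheno), function(tr) {
      m <- res$pheno[[tr]]$means
      cbind(trait = tr, m)
    }))
    utils::write.table(means_out,
                       file.path(config$out_dir, "predicted_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(res$pheno, function(a) {
        list(vc = as.list(a$vc), h2 = a$h2,
             wald = a$wald[c("stat", "df", "p")],
             max_lsd = a$max_lsd$lsd)
      }),
      file.path(config$out_dir, "variance_components.json"),
      auto_unbox = TRUE, digits = NA)
    summary$pheno <- lapply(res$pheno, function(a)
      list(h2 = a$h2, wald = a$wald$stat))
  }

  # ---- association ----------------------------------------------------
  if ("assoc" %in% config$stages) {
    if (is.null(res$pheno)) stop("stage assoc needs stage pheno",
                                 call. = FALSE)
    say("stage assoc")
    G <- res$het_filter$genotypes %||% res$panel_sim$genotypes
    # line labels -> accession labels (same order by construction)
    acc_of_line <- stats::setNames(rownames(res$panel_sim$genotypes),
                                   sprintf("line%03d",
                                           seq_len(nrow(res$panel_sim$genotypes))))
    Q <- if (!is.null(res$structure)) res$structure$Q else NULL
    if (is.null(Q) && !quiet) {
      message("structure stage disabled: association runs without Q covariates")
    }
    kin <- vanraden_kinship(G)
    res$assoc <- lapply(res$pheno, function(a) {
      m <- a$means
      y <- stats::setNames(m$mean_sqrt, acc_of_line[as.character(m$line)])
      y <- y[!is.na(y) & names(y) %in% rownames(G)]
      assoc_scan(y, G, Q = Q, kinship = kin,
                 kw_alpha = config$kw_alpha, mm_alpha = config$mm_alpha)
    })
    res$report <- intersect_and_report(res$assoc, map = res$panel_sim$map)
    for (tr in names(res$assoc)) {
      utils::write.table(res$assoc[[tr]],
                         file.path(config$out_dir,
                                   sprintf("assoc_%s.tsv", tr)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(res$report$manhattan,
                       file.path(config$out_dir, "manhattan.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$assoc <- list(hit_counts = as.list(res$report$counts),
                          shared_all = res$report$shared_all)
  }

  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  res$summary <- summary
  say("run complete: ", config$out_dir)
  invisible(res)
}

#' Validate pipeline input files
#'
#' Schema checks for the plain-text exchange formats: FASTA/FASTQ
#' well-formedness (via Biostrings), genotype calls within the
#' AA/AB/BB/NA vocabulary, positive integer map positions, and
#' non-negative trial counts.  The first violation per file is
#' reported with its location.
#'
#' @param paths named list/vector of file paths; recognised names:
#'   `reference` (FASTA), `consensus` (FASTQ, may be a vector),
#'   `genotypes`, `map`, `trial` (CSV).
#' @return data.frame: file, check, ok, detail.  Zero `ok = FALSE`
#'   rows mean a clean report.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  out <- list()
  add <- function(file, check, ok, detail = "") {
    out[[length(out) + 1]] <<- data.frame(file = file, check = check,
                                          ok = ok, detail = detail)
  }
  if (!is.null(paths$reference)) {
    ok <- tryCatch({
      Biostrings::readDNAStringSet(paths$reference); TRUE
    }, error = function(e) e)
    add(paths$reference, "fasta_wellformed", isTRUE(ok),
        if (isTRUE(ok)) "" else conditionMessage(ok))
  }
  for (fq in paths$consensus) {
    ok <- tryCatch({
      Biostrings::readQualityScaledDNAStringSet(fq,
                                                quality.scoring = "phred")
      # structural scan of the 4-line records: Biostrings recycles
      # short quality strings, so length mismatches need a line check
      lines <- readLines(fq)
      if (length(lines) %% 4 != 0) {
        simpleError("truncated record at end of file")
      } else {
        res <- TRUE
        for (r in seq_len(length(lines) / 4)) {
          l <- lines[(r - 1) * 4 + 1:4]
          if (!startsWith(l[1], "@") || !startsWith(l[3], "+")) {
            res <- simpleError(sprintf("line %d: malformed record header",
                                       (r - 1) * 4 + 1))
            break
          }
          if (nchar(l[2]) != nchar(l[4])) {
            res <- simpleError(sprintf(
              "line %d: quality length %d != sequence length %d",
              (r - 1) * 4 + 4, nchar(l[4]), nchar(l[2])))
            break
          }
        }
        res
      }
    }, error = function(e) e)
    add(fq, "fastq_wellformed", isTRUE(ok),
        if (isTRUE(ok)) "" else conditionMessage(ok))
  }
  if (!is.null(paths$genotypes)) {
    g <- tryCatch(read_genotype_csv(paths$genotypes),
                  error = function(e) e)
    if (inherits(g, "error")) {
      add(paths$genotypes, "genotype_readable", FALSE, conditionMessage(g))
    } else {
      bad <- which(!(g %in% GENO_CALLS) & !is.na(g))
      if (length(bad)) {
        i <- arrayInd(bad[1], dim(g))
        add(paths$genotypes, "genotype_vocabulary", FALSE,
            sprintf("call '%s' at accession %s, marker %s", g[bad[1]],
                    rownames(g)[i[1]], colnames(g)[i[2]]))
      } else {
        add(paths$genotypes, "genotype_vocabulary", TRUE)
      }
    }
  }
  if (!is.null(paths$map)) {
    mp <- tryCatch(read_marker_map_csv(paths$map), error = function(e) e)
    if (inherits(mp, "error")) {
      add(paths$map, "map_readable", FALSE, conditionMessage(mp))
    } else {
      bad <- which(is.na(mp$pos) | mp$pos < 1)
      add(paths$map, "map_positions_positive", length(bad) == 0,
          if (length(bad)) sprintf("row %d: pos must be a positive integer",
                                   bad[1]) else "")
    }
  }
  if (!is.null(paths$trial)) {
    tr <- tryCatch(read_trial_csv(paths$trial), error = function(e) e)
    if (inherits(tr, "error")) {
      add(paths$trial, "trial_readable", FALSE, conditionMessage(tr))
    } else {
      bad <- which(is.na(tr$alate) | is.na(tr$apterous) |
                     tr$alate < 0 | tr$apterous < 0)
      add(paths$trial, "trial_counts_nonnegative", length(bad) == 0,
          if (length(bad)) sprintf("row %d: negative or missing count",
                                   bad[1]) else "")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
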
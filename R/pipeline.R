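# End-to-end orchestration: promoters -> motif scan -> CGI -> stacking
# energy -> classification -> convergent pair -> MRE -> statistics, with a
# single structured, reproducible report.

#' Assemble a pipeline configuration
#'
#' @param promoter_fasta Path to the promoter FASTA (mandatory).
#' @param mrna_fasta,ncrna_fasta Optional paths to the convergent transcript
#'   pair (mRNA sense and ncRNA); both are needed for the heteroduplex stage.
#' @param mature_mirna_fasta Optional mature-miRNA FASTA (RNA alphabet) for
#'   similarity search and MRE calling.
#' @param nrf1_pfm,znf143_pfm Optional JASPAR PFM paths added to the catalog.
#' @param cgi CGI parameters ([cgi_params()]).
#' @param scoring Alignment scoring ([alignment_scoring()]).
#' @param energy_table_path Path to the stacking-energy TSV; default packaged.
#' @param energy_band Length-2 numeric, low-energy band in kcal/mol.
#' @param smoothing_window Profile smoothing window in steps.
#' @param min_segment_length,min_segment_identity Thresholds for the
#'   complementary-segment stage.
#' @param motifs_of_interest Motifs whose incidence is tested across
#'   promoters.
#' @param n_permutations Permutations for energy co-localization.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional output directory; when given, the report (JSON)
#'   and per-stage TSV/BED mirrors are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(promoter_fasta,
                            mrna_fasta = NULL, ncrna_fasta = NULL,
                            mature_mirna_fasta = NULL,
                            nrf1_pfm = NULL, znf143_pfm = NULL,
                            cgi = cgi_params(),
                            scoring = alignment_scoring(),
                            energy_table_path = NULL,
                            energy_band = c(-7.0, -6.5),
                            smoothing_window = 25L,
                            min_segment_length = 20L,
                            min_segment_identity = 70,
                            motifs_of_interest = c("TATA-box", "INR", "DTIE"),
                            n_permutations = 200L,
                            seed = 1L,
                            out_dir = NULL) {
  if (missing(promoter_fasta) || is.null(promoter_fasta)) {
    stop("promoter_fasta is mandatory", call. = FALSE)
  }
  structure(list(
    promoter_fasta = promoter_fasta, mrna_fasta = mrna_fasta,
    ncrna_fasta = ncrna_fasta, mature_mirna_fasta = mature_mirna_fasta,
    nrf1_pfm = nrf1_pfm, znf143_pfm = znf143_pfm,
    cgi = cgi, scoring = scoring,
    energy_table_path = energy_table_path, energy_band = energy_band,
    smoothing_window = as.integer(smoothing_window),
    min_segment_length = as.integer(min_segment_length),
    min_segment_identity = min_segment_identity,
    motifs_of_interest = motifs_of_interest,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

# Internal: flatten an alignment_result for the report.
segment_report <- function(res) {
  if (is.null(res)) return(NULL)
  res[c("a_start", "a_end", "b_start", "b_end", "aligned_a", "aligned_b",
        "score", "matches", "alignment_length", "identity_percent")]
}

#' Run the full regulatory-characterization pipeline
#'
#' Stages run in order: read promoters, scan the motif catalog, detect CpG
#' islands, profile stacking energy (with motif co-localization), classify
#' promoters, analyse the convergent transcript pair, call MREs against the
#' mature-miRNA set, and test motif-incidence differences. Optional stages
#' whose inputs are absent are skipped with a notice in the report, never an
#' abort. The run is deterministic given the configuration and inputs.
#'
#' @param config A [pipeline_config].
#' @return A list of class `regulatory_report`; when `config$out_dir` is set
#'   the report JSON, the configuration echo and per-stage TSV/BED files are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$promoter_fasta)) {
    stop("promoter FASTA not found: ", config$promoter_fasta, call. = FALSE)
  }
  notices <- character(0)
  promoters <- read_fasta(config$promoter_fasta)
  catalog <- motif_catalog(nrf1_pfm = config$nrf1_pfm,
                           znf143_pfm = config$znf143_pfm)

  hits <- do.call(rbind, unlist(lapply(promoters, function(p) {
    lapply(catalog, function(m) {
      if (m$kind == "consensus") scan_consensus(p, m) else scan_pwm(p, m)
    })
  }), recursive = FALSE))
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL

  incidence <- motif_incidence_table(promoters, catalog)

  cgi <- do.call(rbind, lapply(promoters, find_cgi, params = config$cgi))
  rownames(cgi) <- NULL

  energy_table <- if (is.null(config$energy_table_path)) {
    read_energy_table()
  } else {
    read_energy_table(config$energy_table_path)
  }
  energy <- lapply(promoters, function(p) {
    if (nchar(p$residues) < 2L) return(NULL)
    profile <- dinucleotide_profile(p, energy_table)
    smoothed <- if (config$smoothing_window <= length(profile$values)) {
      smooth_profile(profile, config$smoothing_window)
    } else {
      profile
    }
    regions <- low_energy_regions(smoothed, config$energy_band[1],
                                  config$energy_band[2])
    p_hits <- hits[hits$seq_id == p$id, , drop = FALSE]
    coloc <- if (nrow(p_hits) > 0L) {
      colocalize_energy(profile, p_hits,
                        n_permutations = config$n_permutations,
                        seed = config$seed)
    } else {
      NULL
    }
    list(seq_id = p$id, mean_energy = mean(profile$values, na.rm = TRUE),
         low_energy_regions = regions, colocalization = coloc)
  })

  annotations <- lapply(promoters, function(p) {
    classify_promoter(p$id,
                      hits[hits$seq_id == p$id, , drop = FALSE],
                      cgi[cgi$seq_id == p$id, , drop = FALSE])
  })

  segment <- NULL
  mre <- NULL
  mir_ranking <- NULL
  if (!is.null(config$mrna_fasta) && !is.null(config$ncrna_fasta)) {
    mrna <- read_fasta(config$mrna_fasta)[[1]]
    ncrna <- read_fasta(config$ncrna_fasta)[[1]]
    segment <- find_complementary_segment(
      mrna, ncrna, config$scoring,
      min_length = config$min_segment_length,
      min_identity = config$min_segment_identity)
    if (is.null(segment)) {
      notices <- c(notices, "no complementary segment met the thresholds")
    }
    if (!is.null(config$mature_mirna_fasta)) {
      mature <- read_fasta(config$mature_mirna_fasta, alphabet = "RNA")
      mre <- do.call(rbind, lapply(mature, function(m) find_mre(mrna, m)))
      rownames(mre) <- NULL
      if (!is.null(segment)) {
        query <- seq_record("segment_b",
                            substr(ncrna$residues, segment$b_start,
                                   segment$b_end))
        mir_ranking <- mir_similarity_search(query, mature, config$scoring)
        attr(mir_ranking, "alignments") <- NULL
      }
    } else {
      notices <- c(notices, "no mature-miRNA set given; MRE stage skipped")
    }
  } else {
    notices <- c(notices,
                 "convergent pair not given; heteroduplex and MRE stages skipped")
  }

  stats_res <- NULL
  motifs_avail <- intersect(config$motifs_of_interest, names(incidence))
  if (nrow(incidence) >= 2L && length(motifs_avail) >= 2L) {
    stats_res <- incidence_significance(incidence, motifs_avail)
  } else {
    notices <- c(notices, "incidence test skipped (needs >= 2 promoters and motifs)")
  }

  report <- structure(list(
    metadata = list(tool = "regchar",
                    version = as.character(utils::packageVersion("regchar")),
                    seed = config$seed),
    notices = notices,
    promoters = names(promoters),
    motif_hits = hits,
    incidence = incidence,
    cgi_regions = cgi,
    energy = energy,
    annotations = lapply(annotations, function(a) {
      list(promoter_id = a$promoter_id, has_tata = a$has_tata,
           has_cgi = a$has_cgi, has_nrf1 = a$has_nrf1,
           has_znf143 = a$has_znf143, class_labels = a$class_labels)
    }),
    segment = segment_report(segment),
    mre_hits = mre,
    mir_ranking = mir_ranking,
    incidence_test = if (is.null(stats_res)) NULL else {
      list(statistic = stats_res$statistic, df = stats_res$df,
           p_value = stats_res$p_value, test_name = stats_res$test_name)
    }
  ), class = "regulatory_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config)
  }
  report
}

# Internal: write the report JSON and per-stage mirrors into out_dir.
write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- unclass(config)
  echo$cgi <- unclass(echo$cgi)
  echo$scoring <- unclass(echo$scoring)
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  utils::write.table(report$motif_hits, file.path(config$out_dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(promoter = rownames(report$incidence),
                           report$incidence),
                     file.path(config$out_dir, "incidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$cgi_regions, file.path(config$out_dir, "cgi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$motif_hits) > 0L) {
    bed <- data.frame(chrom = report$motif_hits$seq_id,
                      start = report$motif_hits$start,
                      end = report$motif_hits$end,
                      name = report$motif_hits$motif_name,
                      score = report$motif_hits$score,
                      strand = report$motif_hits$strand)
    write_bed(bed, file.path(config$out_dir, "hits.bed"))
  }
  invisible(NULL)
}

#' @export
print.regulatory_report <- function(x, ...) {
  cat("<regulatory_report>\n")
  cat("  promoters:", length(x$promoters), "\n")
  cat("  motif hits:", nrow(x$motif_hits), "\n")
  cat("  CpG islands:", if (is.null(x$cgi_regions)) 0L else nrow(x$cgi_regions), "\n")
  if (!is.null(x$segment)) {
    cat(sprintf("  complementary segment: %d nt, %.1f%% identity\n",
                x$segment$alignment_length, x$segment$identity_percent))
  }
  if (!is.null(x$incidence_test)) {
    cat(sprintf("  incidence test: F = %.3g, p = %.3g\n",
                x$incidence_test$statistic, x$incidence_test$p_value))
  }
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}
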
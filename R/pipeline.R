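# End-to-end orchestration: discovery (novelty filter + SEP annotation) and
# quantitative analysis, each from a single config, writing TSV reports and
# a machine-readable JSON run summary.

#' Discovery/quantification run configuration
#'
#' Collects all module parameters with the pipeline's identification
#' defaults: 0.02 Da product-ion tolerance, at least 4 consecutive b/y ions,
#' at least 40% ion coverage, minimum peptide length 8, q-value at most 0.01,
#' differential thresholds p <= 0.05 and |log2FC| >= 1, 8 clusters,
#' fuzzifier 2.
#'
#' @param seed Integer seed for all seeded stages.
#' @param tol_da,min_consecutive,min_coverage,min_len,q_max,il_collapse
#'   Filter parameters (see [filter_params()]).
#' @param alpha,lfc_min Differential-call thresholds.
#' @param clusters,fuzzifier Fuzzy c-means parameters.
#' @param auc_contrast Grade contrast for per-SEP AUC.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, tol_da = 0.02, min_consecutive = 4L,
                       min_coverage = 0.40, min_len = 8L, q_max = 0.01,
                       il_collapse = FALSE, alpha = 0.05, lfc_min = 1,
                       clusters = 8L, fuzzifier = 2,
                       auc_contrast = "II_vs_III+IV") {
  structure(as.list(environment()), class = "run_config")
}

#' Run the discovery stage end-to-end
#'
#' Reads the reference proteome, SEP database, spectra and PSM table,
#' applies the four-criterion novelty filter, annotates the surviving SEPs
#' and writes `psm_filter_report.tsv`, `identified_seps.tsv`,
#' `sep_annotations.tsv` and `run_summary.json` to `out_dir`.
#'
#' @param reference_fasta,sep_fasta,mgf,psm_tsv Input paths.
#' @param out_dir Output directory (created if needed).
#' @param cfg A `run_config`.
#' @return The run summary, invisibly (list with gate counts, identified SEP
#'   count and annotation class tables).
#' @export
run_discovery <- function(reference_fasta, sep_fasta, mgf, psm_tsv,
                          out_dir, cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_fasta(reference_fasta)
  sep_db <- read_sep_db(sep_fasta)
  spectra <- read_mgf(mgf)
  psms <- read_psm_table(psm_tsv)
  idx <- build_reference_index(reference)
  params <- filter_params(q_max = cfg$q_max, min_len = cfg$min_len,
                          min_consecutive = cfg$min_consecutive,
                          min_coverage = cfg$min_coverage,
                          tol_da = cfg$tol_da, il_collapse = cfg$il_collapse)
  rep <- filter_candidates(psms, spectra, idx, sep_db, params)
  ann <- annotate_seps(sep_db, rep$sep_peptides)
  .write_report(rep$psm_report, file.path(out_dir, "psm_filter_report.tsv"))
  .write_report(rep$identified_seps, file.path(out_dir, "identified_seps.tsv"))
  .write_report(ann, file.path(out_dir, "sep_annotations.tsv"))
  gate_counts <- as.list(table(rep$psm_report$reason))
  summary <- list(stage = "discovery",
                  n_psms = nrow(rep$psm_report),
                  gate_counts = gate_counts,
                  n_identified_seps = nrow(rep$identified_seps),
                  annotation = annotation_summary(ann),
                  params = params)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Run the quantitative stage end-to-end
#'
#' Normalization, imputation, per-patient fold changes, differential calls,
#' grade-trend profiles, fuzzy c-means clustering and per-SEP AUC; writes
#' `normalized_matrix.tsv`, `fold_changes.tsv`, `de_results.tsv`,
#' `cluster_memberships.tsv`, `auc_results.tsv` and `run_summary.json`.
#'
#' @param quant_tsv,samples_tsv Input paths.
#' @param out_dir Output directory (created if needed).
#' @param cfg A `run_config`.
#' @return List with the computed objects (`de`, `fcs`, `clusters`, `auc`)
#'   and the written summary, invisibly.
#' @export
run_quant_analysis <- function(quant_tsv, samples_tsv, out_dir,
                               cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- read_quant_matrix(quant_tsv, samples_tsv)
  qn <- normalize_total_abundance(q)
  qi <- impute_low_abundance(qn, seed = cfg$seed)
  fcs <- pairwise_fold_change(qi)
  de <- differential_call(qi, alpha = cfg$alpha, lfc_min = cfg$lfc_min)
  prof <- grade_trend_profiles(fcs, qi$samples)
  cl <- fuzzy_cmeans(prof, c = cfg$clusters, m = cfg$fuzzifier, seed = cfg$seed)
  auc <- auc_by_grade(fcs, qi$samples, contrast = cfg$auc_contrast)
  write_quant_matrix(qi, file.path(out_dir, "normalized_matrix.tsv"))
  .write_report(fcs, file.path(out_dir, "fold_changes.tsv"))
  .write_report(de, file.path(out_dir, "de_results.tsv"))
  memb <- data.frame(accession = rownames(cl$membership),
                     cluster = cl$hard, cl$membership,
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(memb)[-(1:2)] <- paste0("m", seq_len(cl$c))
  .write_report(memb, file.path(out_dir, "cluster_memberships.tsv"))
  .write_report(auc, file.path(out_dir, "auc_results.tsv"))
  summary <- list(stage = "quant",
                  n_seps = nrow(qi$values),
                  n_patients = length(unique(qi$samples$patient_id)),
                  n_up = sum(de$call == "up"), n_down = sum(de$call == "down"),
                  n_clusters = cl$c, fcm_iterations = cl$iterations,
                  auc_contrast = cfg$auc_contrast,
                  params = cfg[c("seed", "alpha", "lfc_min", "clusters", "fuzzifier")])
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(de = de, fcs = fcs, clusters = cl, auc = auc,
                 summary = summary, matrix = qi))
}
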
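# Peptide-novelty filtering: exclusion of peptides identical to any annotated
# reference protein, of short peptides, and of PSMs failing the spectral
# criteria; survivors are aggregated to SEP-level identifications.

#' Build a reference proteome index for substring queries
#'
#' @param proteome data.frame from [read_fasta()] (columns `header`,
#'   `sequence`).
#' @return A `reference_index` holding the record sequences and an
#'   I/L-collapsed shadow (both residues mapped to one symbol) for
#'   isobaric-aware matching.
#' @export
build_reference_index <- function(proteome) {
  if (is.null(proteome) || nrow(proteome) == 0L) stop("empty reference proteome")
  seqs <- toupper(proteome$sequence)
  structure(list(sequences = seqs,
                 il_sequences = chartr("I", "L", seqs),
                 accessions = proteome$header),
            class = "reference_index")
}

#' Is a peptide sequence annotated in the reference?
#'
#' True iff the bare sequence (modifications ignored) occurs as an exact
#' substring of at least one reference record. Queries never span records.
#' With `il_mode = TRUE`, isoleucine and leucine are treated as equivalent
#' (they are isobaric and indistinguishable by standard MS).
#'
#' @param peptide Uppercase peptide sequence or `modified_peptide`.
#' @param idx A `reference_index`.
#' @param il_mode Collapse I/L before matching (default FALSE: "identical
#'   peptide sequence" is read literally).
#' @return Logical scalar.
#' @export
peptide_is_annotated <- function(peptide, idx, il_mode = FALSE) {
  if (inherits(peptide, "modified_peptide")) peptide <- peptide$sequence
  if (il_mode)
    any(grepl(chartr("I", "L", peptide), idx$il_sequences, fixed = TRUE))
  else
    any(grepl(peptide, idx$sequences, fixed = TRUE))
}

#' Default filtering parameters
#'
#' The identification thresholds: PSM q-value at most 0.01 (FDR < 1%),
#' peptide length at least 8 residues, at least 4 consecutive b or y ions,
#' at least 40% b/y ion coverage, 0.02 Da product-ion tolerance.
#'
#' @param q_max,min_len,min_consecutive,min_coverage,tol_da,il_collapse
#'   Override any threshold.
#' @return Named list of parameters.
#' @export
filter_params <- function(q_max = 0.01, min_len = 8L, min_consecutive = 4L,
                          min_coverage = 0.40, tol_da = 0.02,
                          il_collapse = FALSE) {
  list(q_max = q_max, min_len = as.integer(min_len),
       min_consecutive = as.integer(min_consecutive),
       min_coverage = min_coverage, tol_da = tol_da,
       il_collapse = isTRUE(il_collapse))
}

#' Filter PSMs to novel-SEP identifications
#'
#' Applies the exclusion gates in order: q-value, annotated-in-reference,
#' peptide length, consecutive b/y ion run, b/y ion coverage. Every excluded
#' PSM is recorded with its first failing gate; surviving peptides are
#' grouped by SEP accession.
#'
#' @param psms A `psm_table` from [read_psm_table()].
#' @param spectra Named list of `spectrum` objects (ids must cover the PSMs).
#' @param idx A `reference_index`.
#' @param sep_db Named list of `sep_entry` from [read_sep_db()].
#' @param params See [filter_params()].
#' @return A `filter_report`: `psm_report` (per-PSM gate outcomes and first
#'   failing reason), `identified_seps` (accession, n_peptides,
#'   n_unique_peptides, peptides), `sep_peptides` (named list of surviving
#'   peptide sequences per SEP), `params`.
#' @export
filter_candidates <- function(psms, spectra, idx, sep_db,
                              params = filter_params()) {
  n <- nrow(psms)
  reason <- character(n)
  longest_run <- integer(n)
  coverage <- numeric(n)
  r_q <- sprintf("q>%g", params$q_max)
  r_len <- sprintf("length<%d", params$min_len)
  r_run <- sprintf("run<%d", params$min_consecutive)
  r_cov <- sprintf("coverage<%g", params$min_coverage)
  for (i in seq_len(n)) {
    pep_seq <- psms$peptide[i]
    # SEP accession sanity: every referenced SEP accession must exist and
    # contain the peptide; violations are configuration errors, not exclusions
    for (acc in psms$accession_list[[i]]) {
      if (is.null(sep_db[[acc]]))
        stop("PSM ", psms$spectrum_id[i], " references unknown SEP accession ", acc)
      if (!grepl(pep_seq, sep_db[[acc]]$aa_sequence, fixed = TRUE))
        stop("peptide ", pep_seq, " is not a substring of SEP ", acc)
    }
    sp <- spectra[[psms$spectrum_id[i]]]
    if (is.null(sp)) stop("no spectrum for PSM ", psms$spectrum_id[i])
    crit <- evaluate_spectrum_criteria(
      modified_peptide(pep_seq, mods = psms$mods[[i]], charge = psms$charge[i]),
      sp, tol_da = params$tol_da,
      min_consecutive = params$min_consecutive,
      min_coverage = params$min_coverage)
    longest_run[i] <- crit$longest_run
    coverage[i] <- crit$ion_coverage
    reason[i] <-
      if (psms$q_value[i] > params$q_max) r_q
      else if (peptide_is_annotated(pep_seq, idx, il_mode = params$il_collapse)) "annotated"
      else if (nchar(pep_seq) < params$min_len) r_len
      else if (!crit$pass_run) r_run
      else if (!crit$pass_coverage) r_cov
      else "pass"
  }
  psm_report <- data.frame(
    spectrum_id = psms$spectrum_id, peptide = psms$peptide,
    q_value = psms$q_value, longest_run = longest_run,
    ion_coverage = coverage, excluded = reason != "pass",
    reason = reason, stringsAsFactors = FALSE)
  surv <- which(reason == "pass")
  sep_peptides <- list()
  for (i in surv) {
    for (acc in psms$accession_list[[i]])
      sep_peptides[[acc]] <- c(sep_peptides[[acc]], psms$peptide[i])
  }
  if (length(sep_peptides))
    sep_peptides <- sep_peptides[order(names(sep_peptides))]
  identified_seps <- data.frame(
    accession = if (length(sep_peptides)) names(sep_peptides) else character(0),
    n_peptides = vapply(sep_peptides, length, 0L),
    n_unique_peptides = vapply(sep_peptides, function(p) length(unique(p)), 0L),
    peptides = vapply(sep_peptides, function(p)
      paste(sort(unique(p)), collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(psm_report = psm_report,
                 identified_seps = identified_seps,
                 sep_peptides = lapply(sep_peptides, unique),
                 params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d PSMs, %d surviving, %d SEPs identified\n",
              nrow(x$psm_report), sum(!x$psm_report$excluded),
              nrow(x$identified_seps)))
  tab <- table(x$psm_report$reason)
  for (r in names(tab)) cat(sprintf("  %-16s %d\n", r, tab[[r]]))
  invisible(x)
}
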
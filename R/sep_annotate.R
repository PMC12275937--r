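# SEP-level characterization: start-codon class, transcript class,
# ProtParam instability index (Guruprasad dipeptide-weight method) and
# MS sequence coverage.

# Dipeptide instability weight values (DIWV) of the published
# Guruprasad/ProtParam instability-index method. Rows: first residue of the
# dipeptide; columns: second residue.
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))

#' Classify a start codon
#'
#' `ATG` is the canonical AUG start; `CTG`, `GTG` and `TTG` are the
#' near-cognate starts (one base away from AUG and able to initiate
#' translation); any other valid DNA codon is `other`.
#'
#' @param codon 3-letter DNA string (`[ACGT]{3}`) or `"unknown"`.
#' @return One of `"canonical_AUG"`, `"near_cognate"`, `"other"`, `"unknown"`.
#' @examples
#' classify_start_codon("ATG")
#' classify_start_codon("CTG")
#' @export
classify_start_codon <- function(codon) {
  if (identical(codon, "unknown") || is.na(codon)) return("unknown")
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("malformed codon: ", codon)
  if (codon == "ATG") "canonical_AUG"
  else if (codon %in% c("CTG", "GTG", "TTG")) "near_cognate"
  else "other"
}

#' Normalize a transcript class label
#'
#' Passes through the database-annotated class, normalizing common synonyms
#' (`mRNA`/`coding` to `protein_coding`, `lnc_RNA`/`lincRNA` to `lncRNA`).
#'
#' @param entry A `sep_entry`, or a bare class string.
#' @return One of `"pseudogene"`, `"protein_coding"`, `"lncRNA"`, `"other"`,
#'   `"unknown"`.
#' @export
classify_transcript <- function(entry) {
  cls <- if (inherits(entry, "sep_entry")) entry$transcript_class else entry
  if (is.na(cls) || !nzchar(cls)) return("unknown")
  key <- tolower(cls)
  switch(key,
         "pseudogene" = "pseudogene",
         "protein_coding" = , "mrna" = , "coding" = "protein_coding",
         "lncrna" = , "lnc_rna" = , "lincrna" = "lncRNA",
         "unknown" = "unknown",
         "other")
}

#' Instability index (ProtParam / Guruprasad dipeptide-weight method)
#'
#' `II = (10 / L) * sum over the L-1 overlapping dipeptides of DIWV(x, y)`.
#' Values above 40 conventionally predict an unstable protein in vitro.
#'
#' @param aa_sequence Uppercase amino-acid sequence, length >= 2, canonical
#'   letters only.
#' @return Dimensionless instability index.
#' @examples
#' instability_index("MKWVTFISLLFLFSSAYS")
#' @export
instability_index <- function(aa_sequence) {
  res <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  if (L < 2L) stop("sequence must have length >= 2")
  bad <- which(!res %in% rownames(.DIWV))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d", res[bad[1]], bad[1]))
  w <- .DIWV[cbind(res[-L], res[-1L])]
  (10 / L) * sum(w)
}

#' MS sequence coverage of a SEP
#'
#' Fraction of SEP residues covered by the union of all placements (all
#' occurrences, possibly overlapping) of the identified peptides.
#'
#' @param sep A `sep_entry`, or a bare amino-acid sequence.
#' @param peptides Character vector of peptide sequences; each must occur in
#'   the SEP sequence.
#' @return Fraction in `[0, 1]`.
#' @export
sep_sequence_coverage <- function(sep, peptides) {
  seqs <- if (inherits(sep, "sep_entry")) sep$aa_sequence else sep
  L <- nchar(seqs)
  covered <- logical(L)
  for (p in unique(peptides)) {
    starts <- gregexpr(p, seqs, fixed = TRUE)[[1]]
    if (starts[1] == -1L)
      stop("peptide ", p, " is not a substring of the SEP sequence")
    for (st in starts) covered[st:(st + nchar(p) - 1L)] <- TRUE
  }
  sum(covered) / L
}

#' Annotate identified SEPs
#'
#' Produces the per-SEP characterization table: start-codon class,
#' transcript class, instability index with the conventional stability call
#' (unstable iff II > 40), and MS sequence coverage from the surviving
#' peptides.
#'
#' @param sep_db Named list of `sep_entry` from [read_sep_db()].
#' @param sep_peptides Named list (accession to peptide character vector),
#'   e.g. the `sep_peptides` field of a [filter_candidates()] report.
#' @return data.frame with columns `accession`, `start_class`,
#'   `transcript_class`, `instability_index`, `stability_call`, `coverage`.
#' @export
annotate_seps <- function(sep_db, sep_peptides) {
  accs <- names(sep_peptides)
  rows <- lapply(accs, function(acc) {
    e <- sep_db[[acc]]
    if (is.null(e)) stop("unknown SEP accession: ", acc)
    ii <- instability_index(e$aa_sequence)
    data.frame(accession = acc,
               start_class = classify_start_codon(e$start_codon),
               transcript_class = classify_transcript(e),
               instability_index = ii,
               stability_call = if (ii > 40) "unstable" else "stable",
               coverage = sep_sequence_coverage(e, sep_peptides[[acc]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), start_class = character(0),
                      transcript_class = character(0),
                      instability_index = numeric(0),
                      stability_call = character(0), coverage = numeric(0))
  out
}

#' Class frequency tables for an annotation table
#'
#' @param ann Output of [annotate_seps()].
#' @return List with `start_class`, `transcript_class` and `stability_call`
#'   count tables plus coverage summary quantiles.
#' @export
annotation_summary <- function(ann) {
  list(n_seps = nrow(ann),
       start_class = as.list(table(ann$start_class)),
       transcript_class = as.list(table(ann$transcript_class)),
       stability_call = as.list(table(ann$stability_call)),
       coverage_gt_10pct = if (nrow(ann)) mean(ann$coverage > 0.10) else NA_real_,
       coverage_gt_50pct = if (nrow(ann)) mean(ann$coverage > 0.50) else NA_real_)
}
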
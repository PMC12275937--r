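# Readers/writers for the formats the pipeline touches: FASTA (reference
# proteome, SEP database), MGF (centroided MS2 spectra), TSV (PSM table,
# quant matrix, reports) and JSON run summaries.

#' Read a FASTA file
#'
#' Wrapped sequence lines are concatenated and trailing `*` stop symbols are
#' stripped (with a warning). Duplicate headers are kept, with a warning.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `header` (full description line, no `>`)
#'   and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(headers))
    warning("duplicate FASTA header(s): ",
            paste(unique(headers[duplicated(headers)]), collapse = ", "))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("'*' stop symbols stripped from ", sum(grepl("*", seqs, fixed = TRUE)),
            " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  data.frame(header = headers, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records data.frame with columns `header`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$header
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse SEP metadata from a FASTA header
#'
#' Parses the pipeline's own header dialect
#' `>ACC|start_codon=XXX|tx_class=YYY|db=ZZZ`. Missing keys yield `"unknown"`;
#' foreign headers never fail (the first `|`-token is taken as accession).
#'
#' @param header FASTA description line (without the leading `>`).
#' @return A `sep_entry` list: `accession`, `start_codon`, `transcript_class`,
#'   `source_db` (and `aa_sequence = NA`, to be filled by the caller).
#' @examples
#' parse_sep_header("S1|start_codon=ATG|tx_class=pseudogene|db=SmProt")
#' @export
parse_sep_header <- function(header) {
  header <- sub("^>", "", header)
  toks <- strsplit(header, "|", fixed = TRUE)[[1]]
  acc <- sub("\\s.*$", "", toks[1])
  kv <- list()
  for (t in toks[-1]) {
    m <- regmatches(t, regexec("^([^=]+)=(.*)$", t))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  pick <- function(key) if (!is.null(kv[[key]]) && nzchar(kv[[key]])) kv[[key]] else "unknown"
  structure(list(accession = acc,
                 aa_sequence = NA_character_,
                 start_codon = pick("start_codon"),
                 transcript_class = pick("tx_class"),
                 source_db = pick("db")),
            class = "sep_entry")
}

#' Read a SEP database FASTA
#'
#' @param path FASTA path; headers in the `parse_sep_header()` dialect.
#' @return Named list of `sep_entry` objects keyed by accession.
#' @export
read_sep_db <- function(path) {
  fa <- read_fasta(path)
  entries <- lapply(seq_len(nrow(fa)), function(i) {
    e <- parse_sep_header(fa$header[i])
    e$aa_sequence <- fa$sequence[i]
    e
  })
  names(entries) <- vapply(entries, `[[`, "", "accession")
  entries
}

#' Construct an MS2 spectrum
#'
#' @param spectrum_id Unique spectrum identifier.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer precursor charge.
#' @param mz,intensity Numeric peak vectors (sorted by m/z on construction).
#' @return A `spectrum` object.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge, mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) && any(mz <= 0)) stop("peak m/z must be > 0")
  if (length(intensity) && any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "spectrum")
}

#' Read an MGF peak-list file
#'
#' Supports `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' headers and `mz intensity` peak lines. `TITLE` becomes the spectrum id;
#' the charge sign suffix (`2+`) is stripped.
#'
#' @param path MGF path.
#' @return Named list of `spectrum` objects keyed by spectrum id.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grep("=", block, fixed = TRUE, value = TRUE)
    pk <- block[!grepl("=", block, fixed = TRUE) & nzchar(trimws(block))]
    getv <- function(key) {
      hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    title <- getv("TITLE")
    pep <- getv("PEPMASS")
    if (is.na(pep)) stop("MGF block ", k, " (", title, ") has no PEPMASS")
    chg <- getv("CHARGE")
    chg <- if (is.na(chg)) 2L else as.integer(sub("[+-]$", "", chg))
    if (is.na(title)) title <- paste0("spectrum_", k)
    peakmat <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric))
    if (is.null(peakmat)) peakmat <- matrix(numeric(0), ncol = 2)
    out[[k]] <- spectrum(title, as.numeric(strsplit(pep, "[ \t]+")[[1]][1]), chg,
                         peakmat[, 1], peakmat[, 2])
  }
  names(out) <- vapply(out, `[[`, "", "spectrum_id")
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.6f %.6f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated with named columns `spectrum_id`, `peptide`, `modifications`
#' (`pos:delta` tokens joined by `;`, or `-` for none), `charge`, `q_value`,
#' `accessions` (`;`-separated). Rows failing to parse raise an error naming
#' the offending line.
#'
#' @param path TSV path.
#' @return data.frame of class `psm_table` with an added list-column `mods`
#'   (parsed modification lists) and `accession_list`.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("spectrum_id", "peptide", "modifications", "charge", "q_value", "accessions")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("PSM table missing required column(s): ", paste(missing_cols, collapse = ", "))
  q <- suppressWarnings(as.numeric(df$q_value))
  if (anyNA(q))
    stop("malformed q_value at line ", which(is.na(q))[1] + 1L, " of ", path)
  if (any(q < 0 | q > 1)) stop("q_value outside [0,1] in ", path)
  chg <- suppressWarnings(as.integer(df$charge))
  if (anyNA(chg))
    stop("malformed charge at line ", which(is.na(chg))[1] + 1L, " of ", path)
  df$q_value <- q
  df$charge <- chg
  df$mods <- lapply(df$modifications, parse_mod_string)
  df$accession_list <- strsplit(df$accessions, ";", fixed = TRUE)
  if (any(!vapply(df$accession_list, length, 0L)))
    stop("PSM with empty accession list in ", path)
  class(df) <- c("psm_table", "data.frame")
  df
}

#' Parse a `pos:delta;pos:delta` modification string
#'
#' @param s Modification string; `"-"` or `""` means none.
#' @return List of `list(pos, delta)`.
#' @export
parse_mod_string <- function(s) {
  if (is.na(s) || s %in% c("-", "")) return(list())
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  lapply(toks, function(t) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed modification token: ", t)
    list(pos = as.integer(parts[1]), delta = as.numeric(parts[2]))
  })
}

.format_mod_string <- function(mods) {
  if (!length(mods)) return("-")
  paste(vapply(mods, function(m) sprintf("%d:%.5f", m$pos, m$delta), ""), collapse = ";")
}

#' Write a PSM table
#'
#' @param psms data.frame with the `read_psm_table()` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c("spectrum_id", "peptide", "modifications", "charge", "q_value", "accessions")
  utils::write.table(as.data.frame(psms)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEP x sample quantification matrix with sample metadata
#'
#' The matrix TSV has the SEP accession in the first column and one column
#' per sample; the samples TSV has columns `sample_id`, `patient_id`,
#' `tissue` (`tumor`/`normal`) and `grade` (`II`/`III`/`IV`). Every patient
#' must contribute exactly one tumor and one normal column. Missing values
#' are encoded as `NA` (empty cells also accepted).
#'
#' @param matrix_path,samples_path TSV paths.
#' @return A `quant_matrix`: list with `values` (numeric matrix, rows = SEPs,
#'   columns = samples) and `samples` (data.frame).
#' @export
read_quant_matrix <- function(matrix_path, samples_path) {
  m <- utils::read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- m[[1]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  quant_matrix(vals, samples)
}

#' Construct (and validate) a quant matrix
#'
#' @param values Numeric SEP x sample matrix (NA = missing); row names are
#'   SEP accessions, column names sample ids.
#' @param samples data.frame with `sample_id`, `patient_id`, `tissue`, `grade`.
#' @return A `quant_matrix` object.
#' @export
quant_matrix <- function(values, samples) {
  need <- c("sample_id", "patient_id", "tissue", "grade")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("samples table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!setequal(colnames(values), samples$sample_id))
    stop("matrix columns and samples table disagree")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  tab <- table(samples$patient_id, samples$tissue)
  bad <- rownames(tab)[tab[, "tumor"] != 1L | tab[, "normal"] != 1L]
  if (length(bad))
    stop("patient(s) without exactly one tumor and one normal sample: ",
         paste(bad, collapse = ", "))
  if (any(values < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(list(values = values, samples = samples), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d SEPs x %d samples (%d patients; %.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$patient_id)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write a quant matrix (and optionally its samples table)
#'
#' @param q A `quant_matrix`.
#' @param matrix_path Output TSV for the value matrix.
#' @param samples_path Optional output TSV for sample metadata.
#' @return `matrix_path`, invisibly.
#' @export
write_quant_matrix <- function(q, matrix_path, samples_path = NULL) {
  df <- data.frame(accession = rownames(q$values), q$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(q$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(matrix_path)
}

# generic TSV report writer used by the pipeline
.write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
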
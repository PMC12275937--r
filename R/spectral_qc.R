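# Spectral quality criteria on b/y fragment ions: annotation of observed
# peaks against the theoretical ladder, longest consecutive ion run, and
# fractional ion coverage. These implement the manual-inspection exclusions
# "fewer than four consecutive b or y ions" and "less than 40% coverage of
# b and y ions" as computable predicates.

#' Annotate a spectrum against a theoretical b/y ladder
#'
#' A theoretical ion is matched iff at least one observed peak lies within
#' `tol_da` of its m/z at any considered charge; when several peaks qualify
#' the nearest in m/z wins, and each theoretical ion is matched at most once.
#'
#' @param ladder A `theoretical_ladder` from [fragment_ladder()].
#' @param s A `spectrum`.
#' @param tol_da Product-ion match tolerance in Da (default 0.02).
#' @return An `ion_matches` object: `matched_b`, `matched_y` (integer index
#'   sets) plus a `detail` data.frame (series, index, charge, theo_mz,
#'   obs_mz, delta_mz).
#' @export
annotate_spectrum <- function(ladder, s, tol_da = 0.02) {
  stopifnot(inherits(ladder, "theoretical_ladder"))
  if (tol_da <= 0) stop("tol_da must be > 0")
  detail <- list()
  match_series <- function(mzmat, series) {
    hits <- integer(0)
    for (i in seq_len(nrow(mzmat))) {
      best <- NULL
      for (ci in seq_len(ncol(mzmat))) {
        theo <- mzmat[i, ci]
        if (!length(s$mz)) next
        d <- abs(s$mz - theo)
        j <- which.min(d)
        if (d[j] <= tol_da && (is.null(best) || d[j] < best$adev)) {
          best <- list(adev = d[j], charge = as.integer(colnames(mzmat)[ci]),
                       theo = theo, obs = s$mz[j])
        }
      }
      if (!is.null(best)) {
        hits <- c(hits, i)
        detail[[length(detail) + 1L]] <<- data.frame(
          series = series, index = i, charge = best$charge,
          theo_mz = best$theo, obs_mz = best$obs,
          delta_mz = best$obs - best$theo)
      }
    }
    hits
  }
  mb <- match_series(ladder$b_mz, "b")
  my <- match_series(ladder$y_mz, "y")
  structure(list(matched_b = mb, matched_y = my,
                 length = ladder$length,
                 detail = if (length(detail)) do.call(rbind, detail) else
                   data.frame(series = character(0), index = integer(0),
                              charge = integer(0), theo_mz = numeric(0),
                              obs_mz = numeric(0), delta_mz = numeric(0))),
            class = "ion_matches")
}

#' Longest run of consecutive matched fragment indices
#'
#' Runs are counted within a single ion series (b or y); the maximum of the
#' two series is returned. A run never mixes b and y ions.
#'
#' @param m An `ion_matches` object.
#' @return Integer run length (0 when nothing matched).
#' @export
longest_consecutive_run <- function(m) {
  runlen <- function(idx) {
    if (!length(idx)) return(0L)
    idx <- sort(unique(idx))
    breaks <- c(0L, which(diff(idx) > 1L), length(idx))
    max(diff(breaks))
  }
  max(runlen(m$matched_b), runlen(m$matched_y))
}

#' Fractional b/y ion coverage
#'
#' `(|matched b| + |matched y|) / (2 * (L - 1))`; an index counts once
#' regardless of how many charge states matched it.
#'
#' @param m An `ion_matches` object.
#' @param L Peptide length (>= 2); defaults to the length recorded in `m`.
#' @return Fraction in `[0, 1]`.
#' @export
ion_coverage <- function(m, L = m$length) {
  if (L < 2) stop("peptide length must be >= 2")
  (length(unique(m$matched_b)) + length(unique(m$matched_y))) / (2 * (L - 1))
}

#' Evaluate the spectral exclusion criteria for one PSM
#'
#' Builds the theoretical ladder for the PSM's (modified) peptide, annotates
#' the spectrum and computes the run/coverage statistics with their pass
#' flags. Both criteria are exclusions stated as "fewer than" / "less than",
#' so a run of exactly `min_consecutive` and coverage of exactly
#' `min_coverage` are retained.
#'
#' @param peptide A `modified_peptide` (or bare sequence).
#' @param s A `spectrum`; its id must equal `spectrum_id` when given.
#' @param spectrum_id Optional id cross-check.
#' @param tol_da Match tolerance (Da).
#' @param min_consecutive Minimum consecutive b/y run to retain (default 4).
#' @param min_coverage Minimum ion coverage to retain (default 0.40).
#' @param charges Fragment charges to consider; defaults to 1, adding 2 when
#'   the precursor charge is >= 3.
#' @return A `spectrum_criteria` list: `longest_run`, `ion_coverage`,
#'   `pass_run`, `pass_coverage`.
#' @export
evaluate_spectrum_criteria <- function(peptide, s, spectrum_id = NULL,
                                       tol_da = 0.02, min_consecutive = 4L,
                                       min_coverage = 0.40, charges = NULL) {
  peptide <- .as_peptide(peptide)
  if (!is.null(spectrum_id) && !identical(spectrum_id, s$spectrum_id))
    stop("PSM spectrum id '", spectrum_id, "' does not match spectrum '",
         s$spectrum_id, "'")
  if (is.null(charges))
    charges <- if (peptide$charge >= 3L) c(1L, 2L) else 1L
  ladder <- fragment_ladder(peptide, charges = charges)
  m <- annotate_spectrum(ladder, s, tol_da = tol_da)
  run <- longest_consecutive_run(m)
  cov <- ion_coverage(m)
  structure(list(longest_run = run, ion_coverage = cov,
                 pass_run = run >= min_consecutive,
                 pass_coverage = cov >= min_coverage,
                 matches = m),
            class = "spectrum_criteria")
}

#' Spectral similarity between two peak lists
#'
#' Cosine similarity of intensity vectors after greedy nearest-peak pairing
#' within `tol_da`: candidate peak pairs are ranked by absolute m/z
#' difference and consumed greedily, each peak used at most once; unpaired
#' peaks contribute their intensity against zero. Scale-invariant and
#' symmetric. Intended for synthetic-standard versus endogenous spectrum
#' concordance checks.
#'
#' @param a,b `spectrum` objects (non-empty).
#' @param tol_da Pairing tolerance in Da.
#' @return Similarity score in `[0, 1]`.
#' @export
spectral_similarity <- function(a, b, tol_da = 0.02) {
  if (!length(a$mz) || !length(b$mz)) stop("spectra must be non-empty")
  cand <- expand.grid(i = seq_along(a$mz), j = seq_along(b$mz))
  cand$d <- abs(a$mz[cand$i] - b$mz[cand$j])
  cand <- cand[cand$d <= tol_da, , drop = FALSE]
  # deterministic, argument-order-invariant tie-break
  cand <- cand[order(cand$d,
                     pmin(a$mz[cand$i], b$mz[cand$j]),
                     pmax(a$mz[cand$i], b$mz[cand$j])), , drop = FALSE]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  pa <- numeric(0); pb <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pa <- c(pa, a$intensity[i]); pb <- c(pb, b$intensity[j])
  }
  va <- c(pa, a$intensity[!used_a], numeric(sum(!used_b)))
  vb <- c(pb, numeric(sum(!used_a)), b$intensity[!used_b])
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}
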
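# Synthetic-data generation: every input the pipeline consumes (reference
# proteome, SEP database, spectra, PSM table, quant matrix) with the
# statistical structure the analysis assumes, plus exact truth tables, so
# the whole pipeline is testable without any external dataset.

.AA_LETTERS <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                 "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: a paired
#' tumor/normal cohort of 18 patients (9 grade II, 3 grade III, 6 grade IV),
#' planted differential effects of 2 log2 units with 0.5 log2-unit noise,
#' and a SEP discovery set in which half the database entries are genuinely
#' novel and half are decoys embedded in the reference proteome.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_reference_proteins Number of reference proteome records.
#' @param n_seps Number of SEP database entries.
#' @param fraction_novel Fraction of SEPs absent from the reference.
#' @param peptide_ion_completeness Probability each b/y ladder ion appears in
#'   a planted-survivor spectrum.
#' @param n_noise_peaks Noise peaks per simulated spectrum.
#' @param mz_jitter_sd m/z jitter SD (Da) on planted fragment peaks.
#' @param n_patients Named counts of patients per grade.
#' @param n_quant_seps SEP count for the quantitative simulation.
#' @param planted_log2fc Planted tumor/normal log2 fold change.
#' @param noise_sd Log2-scale measurement noise SD.
#' @param frac_up,frac_down Fractions of SEPs with planted up/down shifts.
#' @param frac_trend_up,frac_trend_down Fractions with grade-monotone trends.
#' @param missing_tau,missing_width,missing_max Logistic-in-log2-intensity
#'   dropout: `P(missing) = missing_max * plogis((missing_tau - log2 x) /
#'   missing_width)`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_reference_proteins = 20L,
                       n_seps = 50L,
                       fraction_novel = 0.5,
                       peptide_ion_completeness = 1.0,
                       n_noise_peaks = 5L,
                       mz_jitter_sd = 0.003,
                       n_patients = c(II = 9L, III = 3L, IV = 6L),
                       n_quant_seps = 200L,
                       planted_log2fc = 2,
                       noise_sd = 0.5,
                       frac_up = 0.10, frac_down = 0.10,
                       frac_trend_up = 0.10, frac_trend_down = 0.10,
                       missing_tau = 17, missing_width = 1, missing_max = 0.3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_reference_proteins >= 1, n_seps >= 1, n_quant_seps >= 1,
            fraction_novel >= 0, fraction_novel <= 1,
            peptide_ion_completeness >= 0, peptide_ion_completeness <= 1,
            missing_max >= 0, missing_max <= 1,
            frac_up + frac_down + frac_trend_up + frac_trend_down <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.random_aa <- function(n) paste(sample(.AA_LETTERS, n, replace = TRUE), collapse = "")

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and emits
#' every fragment carrying 0 to `max_missed` internal missed cleavages.
#'
#' @param sequence Protein/peptide sequence.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @return Character vector of peptides, ordered by start position then span.
#' @examples
#' tryptic_digest("AKRPK", max_missed = 0)
#' @export
tryptic_digest <- function(sequence, max_missed = 2L) {
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & res[pmin(cut_after + 1L, L)] != "P" |
                           cut_after == L]
  bounds <- c(0L, cut_after[cut_after < L], L)  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nfrag <- length(starts)
  out <- character(0)
  for (i in seq_len(nfrag)) {
    for (mm in 0:min(max_missed, nfrag - i)) {
      out <- c(out, substr(sequence, starts[i], ends[i + mm]))
    }
  }
  out
}

#' Simulate a fragmentation spectrum for a peptide
#'
#' Each singly-charged b/y ladder ion is included independently with
#' probability `completeness`, its m/z jittered by a truncated
#' `Normal(0, jitter_sd)` (at most 0.015 Da); `n_noise` uniform noise peaks
#' are added at least 0.1 Th away from every ladder ion. Intensities are
#' log-normal, noise an order of magnitude below signal.
#'
#' @param p A `modified_peptide` or sequence.
#' @param completeness Ladder completeness probability in `[0, 1]`.
#' @param n_noise Number of noise peaks.
#' @param jitter_sd m/z jitter SD (must stay below 0.01 so fixtures remain
#'   matchable at the 0.02 Da tolerance).
#' @param seed Integer RNG seed.
#' @param spectrum_id Id for the returned spectrum.
#' @return A `spectrum`.
#' @export
simulate_spectrum <- function(p, completeness = 1, n_noise = 5L,
                              jitter_sd = 0.003, seed = 1L,
                              spectrum_id = "sim") {
  if (completeness < 0 || completeness > 1) stop("completeness must be in [0,1]")
  if (jitter_sd >= 0.01)
    stop("jitter_sd must be < 0.01 (half the 0.02 Da match tolerance)")
  p <- .as_peptide(p)
  ladder <- fragment_ladder(p, charges = 1L)
  theo <- c(ladder$b_mz[, 1], ladder$y_mz[, 1])
  .with_seed(seed, {
    keep <- stats::runif(length(theo)) < completeness
    mz <- theo[keep]
    if (length(mz) && jitter_sd > 0) {
      j <- stats::rnorm(length(mz), 0, jitter_sd)
      j <- pmin(pmax(j, -0.015), 0.015)
      mz <- mz + j
    }
    inten <- stats::rlnorm(length(mz), meanlog = log(1e4), sdlog = 0.8)
    lo <- 100; hi <- max(theo) + 200
    noise_mz <- numeric(0)
    while (length(noise_mz) < n_noise) {
      cand <- stats::runif(n_noise - length(noise_mz), lo, hi)
      ok <- vapply(cand, function(x) all(abs(x - theo) >= 0.1), TRUE)
      noise_mz <- c(noise_mz, cand[ok])
    }
    noise_int <- stats::rlnorm(length(noise_mz), meanlog = log(1e3), sdlog = 0.8)
    spectrum(spectrum_id,
             precursor_mz = (ladder$neutral_mass + p$charge * 1.007276) / p$charge,
             precursor_charge = p$charge,
             mz = c(mz, noise_mz), intensity = c(inten, noise_int))
  })
}

# ladder m/z values must be mutually separated so a peak planted for one ion
# can never be attributed to another (needed for constructive truth tables)
.ladder_well_separated <- function(sequence, min_gap = 0.05) {
  l <- fragment_ladder(sequence, charges = 1L)
  mz <- sort(c(l$b_mz[, 1], l$y_mz[, 1]))
  all(diff(mz) > min_gap)
}

# a spectrum containing exactly the chosen b-ion indices, no jitter/noise
.exact_ion_spectrum <- function(sequence, b_indices, spectrum_id) {
  l <- fragment_ladder(sequence, charges = 1L)
  mz <- l$b_mz[b_indices, 1]
  spectrum(spectrum_id, precursor_mz = (l$neutral_mass + 2 * 1.007276) / 2,
           precursor_charge = 2L, mz = mz,
           intensity = rep(1e4, length(mz)))
}

# pick a tryptic peptide of `seqs` with length in [lo, hi]; NA when none
.pick_tryptic <- function(seqs, lo = 8L, hi = 30L, max_missed = 2L) {
  peps <- unique(tryptic_digest(seqs, max_missed = max_missed))
  peps <- peps[nchar(peps) >= lo & nchar(peps) <= hi]
  if (!length(peps)) return(NA_character_)
  sample(peps, 1L)
}

#' Simulate a discovery input bundle with exact ground truth
#'
#' Generates a random reference proteome, a SEP database in which a
#' configured fraction is novel (constructively: no tryptic peptide of
#' length >= 8 occurs in the reference) and the remainder are decoys whose
#' sequences are embedded verbatim in reference records, plus PSMs and
#' spectra exercising every exclusion gate, and a truth table stating which
#' SEP accessions must survive the filter and why every other is excluded.
#'
#' Planted survivors carry complete, exactly placed fragment ladders and
#' sub-threshold q-values; planted exclusions each fail exactly one gate
#' (annotated decoy, high q-value, short peptide, broken ion run, or low ion
#' coverage) so the construction itself is the oracle.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Directory for the generated files (created if needed).
#' @return List with file paths (`reference_fasta`, `sep_fasta`, `mgf`,
#'   `psm_tsv`, `truth_tsv`) and the in-memory `truth` data.frame
#'   (`accession`, `planted`, `expect_identified`, `expect_reason`).
#' @export
simulate_discovery_bundle <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(cfg$seed + 1L, {
    reference <- data.frame(
      header = sprintf("REF_%03d", seq_len(cfg$n_reference_proteins)),
      sequence = vapply(seq_len(cfg$n_reference_proteins),
                        function(i) .random_aa(sample(200:400, 1L)), ""),
      stringsAsFactors = FALSE)
    ref_idx <- build_reference_index(reference)

    n_novel <- round(cfg$n_seps * cfg$fraction_novel)
    n_decoy <- cfg$n_seps - n_novel
    # roles among novel SEPs: survivors plus one planted failure per gate
    roles <- rep("survivor", n_novel)
    fail_roles <- c("q_fail", "length_fail", "run_fail", "coverage_fail")
    n_fail <- min(length(fail_roles), max(0L, n_novel - 1L))
    if (n_fail > 0L) roles[seq_len(n_fail)] <- fail_roles[seq_len(n_fail)]
    roles <- sample(roles)

    make_novel <- function(role) {
      for (try in 1:200) {
        s <- .random_aa(sample(20:100, 1L))
        peps <- unique(tryptic_digest(s))
        long <- peps[nchar(peps) >= 8 & nchar(peps) <= 30]
        short <- peps[nchar(peps) >= 5 & nchar(peps) <= 7]
        if (any(vapply(peps[nchar(peps) >= 8], peptide_is_annotated, TRUE,
                       idx = ref_idx))) next  # not novel; resample
        if (role == "length_fail") {
          short <- short[!vapply(short, peptide_is_annotated, TRUE, idx = ref_idx)]
          if (!length(short)) next
        }
        if (!length(long)) next
        pep <- if (role == "length_fail") sample(short, 1L) else sample(long, 1L)
        if (role %in% c("run_fail", "coverage_fail") &&
            !.ladder_well_separated(pep)) next
        return(list(sequence = s, peptide = pep))
      }
      stop("could not construct a novel SEP after bounded retries")
    }
    make_decoy <- function() {
      for (try in 1:200) {
        rec <- sample(reference$sequence, 1L)
        len <- sample(20:100, 1L)
        st <- sample(nchar(rec) - len, 1L)
        s <- substr(rec, st, st + len - 1L)
        pep <- .pick_tryptic(s)
        if (!is.na(pep)) return(list(sequence = s, peptide = pep))
      }
      stop("could not construct a decoy SEP after bounded retries")
    }

    start_pool <- c("ATG", "CTG", "GTG", "TTG", "ACG", "AGG")
    start_prob <- c(0.55, 0.10, 0.10, 0.05, 0.10, 0.10)
    tx_pool <- c("pseudogene", "protein_coding", "lncRNA", "other")
    tx_prob <- c(0.49, 0.27, 0.10, 0.14)

    seps <- list(); truth <- list(); psms <- list(); spectra <- list()
    scan <- 0L
    for (k in seq_len(cfg$n_seps)) {
      acc <- sprintf("SEP_%03d", k)
      is_novel <- k <= n_novel
      role <- if (is_novel) roles[k] else "decoy"
      gen <- if (is_novel) make_novel(role) else make_decoy()
      seps[[k]] <- data.frame(
        header = sprintf("%s|start_codon=%s|tx_class=%s|db=%s", acc,
                         sample(start_pool, 1L, prob = start_prob),
                         sample(tx_pool, 1L, prob = tx_prob),
                         sample(c("SmProt", "OpenProt"), 1L)),
        sequence = gen$sequence, stringsAsFactors = FALSE)
      scan <- scan + 1L
      sid <- sprintf("scan_%04d", scan)
      pep <- gen$peptide
      L <- nchar(pep)
      q <- if (role == "q_fail") stats::runif(1, 0.02, 0.05)
           else stats::runif(1, 1e-4, 9e-3)
      sp <- switch(role,
        run_fail = .exact_ion_spectrum(pep, seq(1L, L - 1L, by = 2L), sid),
        coverage_fail = .exact_ion_spectrum(pep, 1:4, sid),
        simulate_spectrum(pep, completeness = cfg$peptide_ion_completeness,
                          n_noise = cfg$n_noise_peaks,
                          jitter_sd = cfg$mz_jitter_sd,
                          seed = cfg$seed + 1000L + scan, spectrum_id = sid))
      spectra[[sid]] <- sp
      psms[[scan]] <- data.frame(
        spectrum_id = sid, peptide = pep, modifications = "-",
        charge = 2L, q_value = signif(q, 4), accessions = acc,
        stringsAsFactors = FALSE)
      reason <- switch(role,
        survivor = "pass", decoy = "annotated",
        q_fail = "q>0.01", length_fail = "length<8",
        run_fail = "run<4", coverage_fail = "coverage<0.4")
      truth[[k]] <- data.frame(
        accession = acc, planted = role,
        expect_identified = identical(role, "survivor"),
        expect_reason = reason, stringsAsFactors = FALSE)
    }
    sep_fa <- do.call(rbind, seps)
    truth_df <- do.call(rbind, truth)
    psm_df <- do.call(rbind, psms)

    paths <- list(reference_fasta = file.path(out_dir, "reference.fasta"),
                  sep_fasta = file.path(out_dir, "sep_db.fasta"),
                  mgf = file.path(out_dir, "spectra.mgf"),
                  psm_tsv = file.path(out_dir, "psms.tsv"),
                  truth_tsv = file.path(out_dir, "truth.tsv"))
    write_fasta(reference, paths$reference_fasta)
    write_fasta(sep_fa, paths$sep_fasta)
    write_mgf(spectra, paths$mgf)
    write_psm_table(psm_df, paths$psm_tsv)
    .write_report(truth_df, paths$truth_tsv)
    c(paths, list(truth = truth_df))
  })
}

#' Simulate a paired tumor/normal quant matrix with planted effects
#'
#' Log-normal baseline intensities; planted up/down SEPs shifted by
#' `planted_log2fc` in tumors of every grade; planted grade-monotone SEPs
#' with a linear log2 trend across grades (spanning `planted_log2fc` from
#' grade II to IV); Gaussian log2-scale noise; missing-not-at-random dropout
#' with logistic probability decreasing in log2 intensity.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Directory for the generated TSVs (created if needed).
#' @return List with `quant_tsv`, `samples_tsv`, `truth_tsv` paths, the
#'   in-memory `quant_matrix` `q` and the `truth` data.frame (`accession`,
#'   `class`, `effect_log2fc`).
#' @export
simulate_quant <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(cfg$seed + 2L, {
    grades <- rep(names(cfg$n_patients), times = cfg$n_patients)
    np <- length(grades)
    patients <- sprintf("P%02d", seq_len(np))
    samples <- data.frame(
      sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
      patient_id = rep(patients, 2L),
      tissue = rep(c("tumor", "normal"), each = np),
      grade = rep(grades, 2L), stringsAsFactors = FALSE)

    ns <- cfg$n_quant_seps
    n_up <- round(ns * cfg$frac_up); n_down <- round(ns * cfg$frac_down)
    n_tu <- round(ns * cfg$frac_trend_up); n_td <- round(ns * cfg$frac_trend_down)
    cls <- c(rep("up", n_up), rep("down", n_down),
             rep("trend_up", n_tu), rep("trend_down", n_td),
             rep("null", ns - n_up - n_down - n_tu - n_td))
    accs <- sprintf("QSEP_%04d", seq_len(ns))
    gidx <- match(grades, names(cfg$n_patients)) - 1L  # II=0, III=1, IV=2
    half_span <- cfg$planted_log2fc / 2
    # per-SEP x patient planted tumor effect in log2 units
    effect <- matrix(0, ns, np)
    effect[cls == "up", ] <- cfg$planted_log2fc
    effect[cls == "down", ] <- -cfg$planted_log2fc
    effect[cls == "trend_up", ] <- rep((gidx - 1) * half_span,
                                       each = sum(cls == "trend_up"))
    effect[cls == "trend_down", ] <- rep(-(gidx - 1) * half_span,
                                         each = sum(cls == "trend_down"))
    baseline <- stats::rnorm(ns, mean = 20, sd = 2)
    noiseT <- matrix(stats::rnorm(ns * np, 0, cfg$noise_sd), ns, np)
    noiseN <- matrix(stats::rnorm(ns * np, 0, cfg$noise_sd), ns, np)
    logT <- baseline + effect + noiseT
    logN <- baseline + noiseN
    vals <- cbind(2^logT, 2^logN)
    rownames(vals) <- accs
    colnames(vals) <- samples$sample_id
    # MNAR dropout: logistic in log2 intensity
    pmiss <- cfg$missing_max *
      stats::plogis((cfg$missing_tau - log2(vals)) / cfg$missing_width)
    drop <- matrix(stats::runif(length(vals)) < pmiss, nrow(vals))
    vals[drop] <- NA_real_
    q <- quant_matrix(vals, samples)
    truth <- data.frame(accession = accs, class = cls,
                        effect_log2fc = ifelse(cls == "up", cfg$planted_log2fc,
                                        ifelse(cls == "down", -cfg$planted_log2fc, 0)),
                        stringsAsFactors = FALSE)
    paths <- list(quant_tsv = file.path(out_dir, "quant.tsv"),
                  samples_tsv = file.path(out_dir, "samples.tsv"),
                  truth_tsv = file.path(out_dir, "quant_truth.tsv"))
    write_quant_matrix(q, paths$quant_tsv, paths$samples_tsv)
    .write_report(truth, paths$truth_tsv)
    c(paths, list(q = q, truth = truth))
  })
}
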
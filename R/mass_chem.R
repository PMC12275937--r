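# Monoisotopic mass bookkeeping: residue/modification masses, neutral peptide
# mass and theoretical b/y fragment ladders.

# Residue monoisotopic masses (Da), standard Unimod/IUPAC values to 6 decimals.
.RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.MASS_WATER  <- 18.010565
.MASS_PROTON <- 1.007276

# Common modification deltas (Da)
.MOD_CARBAMIDOMETHYL <- 57.02146
.MOD_OXIDATION       <- 15.99491
.MOD_ACETYL          <- 42.01057

#' Construct a modified peptide
#'
#' A peptide is an uppercase amino-acid string over the 20 canonical letters
#' plus a (possibly empty) set of positioned mass modifications. Position 0
#' denotes the peptide N-terminus; positions 1..L denote residues.
#'
#' @param sequence Uppercase amino-acid string.
#' @param mods List of `list(pos = <int>, delta = <Da>)`, or a two-column
#'   data.frame with columns `pos` and `delta`. At most one mod per position.
#' @param charge Positive integer precursor charge.
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("ACDK", mods = list(list(pos = 2, delta = 57.02146)))
#' @export
modified_peptide <- function(sequence, mods = list(), charge = 2L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  letters1 <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!letters1 %in% names(.RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d", letters1[bad[1]], bad[1]))
  if (is.data.frame(mods))
    mods <- lapply(seq_len(nrow(mods)), function(i) list(pos = mods$pos[i], delta = mods$delta[i]))
  L <- nchar(sequence)
  pos <- vapply(mods, function(m) as.integer(m$pos), integer(1))
  if (length(pos)) {
    if (any(pos < 0L | pos > L)) stop("mod position out of [0, length]")
    if (anyDuplicated(pos)) stop("at most one mod per position")
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1)
    stop("charge must be a positive integer")
  structure(list(sequence = sequence,
                 mods = mods,
                 charge = as.integer(charge)),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  modtxt <- if (length(x$mods))
    paste(vapply(x$mods, function(m) sprintf("%d:%+.5f", m$pos, m$delta), ""), collapse = ";")
  else "none"
  cat(sprintf("<modified_peptide> %s (z=%d, mods: %s)\n", x$sequence, x$charge, modtxt))
  invisible(x)
}

.as_peptide <- function(p) {
  if (inherits(p, "modified_peptide")) p else modified_peptide(p)
}

# per-position mod deltas as a numeric vector indexed 0..L (returned length L+1)
.mod_vector <- function(p) {
  L <- nchar(p$sequence)
  v <- numeric(L + 1L)
  for (m in p$mods) v[as.integer(m$pos) + 1L] <- m$delta
  v
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses, modification deltas and one water
#' (18.010565 Da) for the termini.
#'
#' @param p A `modified_peptide` or bare sequence string.
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass("LNEEASEEILK")
#' @export
peptide_neutral_mass <- function(p) {
  p <- .as_peptide(p)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sum(.RESIDUE_MASS[res]) + sum(.mod_vector(p)) + .MASS_WATER
}

#' Theoretical b/y fragment ladder
#'
#' Computes neutral b- and y-fragment masses for cleavage at every backbone
#' position and their m/z at the requested charges. Neutral `b_i` is the sum
#' of the first `i` residue masses (plus mods located there; an N-terminal mod
#' belongs to every b ion), neutral `y_j` is the sum of the last `j` residues
#' plus water (plus mods located there). `m/z = (neutral + z * 1.007276) / z`.
#'
#' @param p A `modified_peptide` or bare sequence (length >= 2).
#' @param charges Integer vector of fragment charges, all >= 1.
#' @return A `theoretical_ladder`: list with `length`, `neutral_mass`,
#'   `b_neutral`, `y_neutral` (length L-1 each) and `b_mz`, `y_mz`
#'   ((L-1) x n_charges matrices, columns named by charge).
#' @examples
#' fragment_ladder("ACDK", charges = 1L)
#' @export
fragment_ladder <- function(p, charges = 1L) {
  p <- .as_peptide(p)
  L <- nchar(p$sequence)
  if (L < 2L) stop("peptide of length 1 has no fragments")
  if (length(charges) < 1L || any(charges < 1)) stop("charges must be non-empty, all >= 1")
  charges <- sort(unique(as.integer(charges)))
  res <- .RESIDUE_MASS[strsplit(p$sequence, "", fixed = TRUE)[[1]]]
  mv <- .mod_vector(p)                     # index 1 = N-term, 1+i = residue i
  site <- res + mv[-1L]                    # residue + its own mod
  b_neutral <- cumsum(site)[-L] + mv[1L]   # N-term mod rides on every b ion
  y_neutral <- rev(cumsum(rev(site)))[-1L] + .MASS_WATER  # y_j = last j residues
  y_neutral <- rev(y_neutral)              # order y_1 .. y_{L-1}
  tomz <- function(neutral) {
    m <- vapply(charges, function(z) (neutral + z * .MASS_PROTON) / z,
                numeric(length(neutral)))
    m <- matrix(m, nrow = length(neutral), dimnames = list(NULL, as.character(charges)))
    m
  }
  structure(list(length = L,
                 neutral_mass = sum(site) + mv[1L] + .MASS_WATER,
                 b_neutral = unname(b_neutral),
                 y_neutral = unname(y_neutral),
                 b_mz = tomz(unname(b_neutral)),
                 y_mz = tomz(unname(y_neutral)),
                 charges = charges),
            class = "theoretical_ladder")
}

#' Default search modification configuration
#'
#' Carbamidomethylation of cysteine fixed; methionine oxidation and
#' protein N-terminal acetylation variable, at most `max_variable`
#' simultaneous variable modifications.
#'
#' @param max_variable Cap on simultaneous variable modifications.
#' @return A `mod_config` list with `fixed`, `variable` and `max_variable`.
#' @export
default_mod_config <- function(max_variable = 3L) {
  mod_config(
    fixed = list(list(name = "carbamidomethyl", target = "C", delta = .MOD_CARBAMIDOMETHYL)),
    variable = list(
      list(name = "oxidation", target = "M", delta = .MOD_OXIDATION),
      list(name = "acetyl", target = "nterm", delta = .MOD_ACETYL)
    ),
    max_variable = max_variable
  )
}

#' Build a modification configuration
#'
#' @param fixed,variable Lists of `list(name, target, delta)`; `target` is a
#'   residue letter or `"nterm"`.
#' @param max_variable Cap on simultaneous variable mods (>= 0).
#' @return A `mod_config` object.
#' @export
mod_config <- function(fixed = list(), variable = list(), max_variable = 3L) {
  if (max_variable < 0) stop("max_variable must be >= 0")
  structure(list(fixed = fixed, variable = variable,
                 max_variable = as.integer(max_variable)),
            class = "mod_config")
}

#' Enumerate modification isoforms of a sequence
#'
#' Applies every fixed modification at all its target sites and enumerates all
#' subsets of variable modification sites up to the configured cap.
#'
#' @param sequence Bare uppercase peptide sequence.
#' @param config A `mod_config` (default [default_mod_config()]).
#' @param charge Charge assigned to the returned peptides.
#' @return List of `modified_peptide` isoforms (always >= 1; the first carries
#'   fixed mods only).
#' @export
apply_fixed_and_variable_mods <- function(sequence, config = default_mod_config(),
                                          charge = 2L) {
  stopifnot(inherits(config, "mod_config"))
  letters1 <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed_mods <- list()
  for (f in config$fixed) {
    sites <- if (identical(f$target, "nterm")) 0L else which(letters1 == f$target)
    for (s in sites) fixed_mods[[length(fixed_mods) + 1L]] <- list(pos = s, delta = f$delta)
  }
  var_sites <- list()
  for (v in config$variable) {
    sites <- if (identical(v$target, "nterm")) 0L else which(letters1 == v$target)
    for (s in sites) var_sites[[length(var_sites) + 1L]] <- list(pos = s, delta = v$delta)
  }
  # drop variable sites colliding with fixed sites (one mod per position)
  fixed_pos <- vapply(fixed_mods, `[[`, integer(1), "pos")
  var_sites <- Filter(function(v) !(v$pos %in% fixed_pos), var_sites)
  nv <- length(var_sites)
  out <- list()
  for (k in 0:min(nv, config$max_variable)) {
    combs <- if (k == 0L) list(integer(0)) else
      asplit(utils::combn(nv, k), 2L)
    for (idx in combs) {
      sel <- var_sites[as.integer(idx)]
      pos <- vapply(sel, `[[`, integer(1), "pos")
      if (anyDuplicated(pos)) next  # two variable mods on the same site
      out[[length(out) + 1L]] <-
        modified_peptide(sequence, mods = c(fixed_mods, sel), charge = charge)
    }
  }
  out
}
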
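# Independent oracles used across the suite: elemental-composition peptide
# masses, a dipeptide-keyed instability lookup, brute-force peak matching and
# brute-force AUC. These deliberately avoid the package's own code paths.

# -- elemental-composition peptide mass oracle -------------------------------
ATOM_MASS <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)

# residue formulas (residue = amino acid - H2O), counts of C,H,N,O,S
RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracle_peptide_mass <- function(seq) {
  counts <- c(0, 2, 0, 1, 0)  # start from one water (H2O)
  for (a in strsplit(seq, "")[[1]]) counts <- counts + RESIDUE_FORMULA[[a]]
  sum(counts * ATOM_MASS[c("C", "H", "N", "O", "S")])
}

random_peptide <- function(min_len = 5, max_len = 25) {
  len <- if (min_len == max_len) min_len else
    sample(seq(min_len, max_len), 1)
  paste(sample(names(RESIDUE_FORMULA), len, replace = TRUE), collapse = "")
}

# -- brute-force peak/ladder matching oracle ---------------------------------
oracle_matched_indices <- function(theo_mz_matrix, peak_mz, tol) {
  which(apply(theo_mz_matrix, 1, function(mzrow)
    any(outer(mzrow, peak_mz, function(a, b) abs(a - b)) <= tol)))
}

# -- brute-force AUC oracle (all positive/negative pairs, ties 0.5) ----------
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# -- dipeptide-keyed instability-index oracle --------------------------------
DIWV_ORACLE <- c(
  "AA" = 1, "AC" = 44.94, "AD" = -7.49, "AE" = 1, "AF" = 1, "AG" = 1, "AH" = -7.49, "AI" = 1,
  "AK" = 1, "AL" = 1, "AM" = 1, "AN" = 1, "AP" = 20.26, "AQ" = 1, "AR" = 1, "AS" = 1,
  "AT" = 1, "AV" = 1, "AW" = 1, "AY" = 1, "CA" = 1, "CC" = 1, "CD" = 20.26, "CE" = 1,
  "CF" = 1, "CG" = 1, "CH" = 33.6, "CI" = 1, "CK" = 1, "CL" = 20.26, "CM" = 33.6, "CN" = 1,
  "CP" = 20.26, "CQ" = -6.54, "CR" = 1, "CS" = 1, "CT" = 33.6, "CV" = -6.54, "CW" = 24.68, "CY" = 1,
  "DA" = 1, "DC" = 1, "DD" = 1, "DE" = 1, "DF" = -6.54, "DG" = 1, "DH" = 1, "DI" = 1,
  "DK" = -7.49, "DL" = 1, "DM" = 1, "DN" = 1, "DP" = 1, "DQ" = 1, "DR" = -6.54, "DS" = 20.26,
  "DT" = -14.03, "DV" = 1, "DW" = 1, "DY" = 1, "EA" = 1, "EC" = 44.94, "ED" = 20.26, "EE" = 33.6,
  "EF" = 1, "EG" = 1, "EH" = -6.54, "EI" = 20.26, "EK" = 1, "EL" = 1, "EM" = 1, "EN" = 1,
  "EP" = 20.26, "EQ" = 20.26, "ER" = 1, "ES" = 20.26, "ET" = 1, "EV" = 1, "EW" = -14.03, "EY" = 1,
  "FA" = 1, "FC" = 1, "FD" = 13.34, "FE" = 1, "FF" = 1, "FG" = 1, "FH" = 1, "FI" = 1,
  "FK" = -14.03, "FL" = 1, "FM" = 1, "FN" = 1, "FP" = 20.26, "FQ" = 1, "FR" = 1, "FS" = 1,
  "FT" = 1, "FV" = 1, "FW" = 1, "FY" = 33.601, "GA" = -7.49, "GC" = 1, "GD" = 1, "GE" = -6.54,
  "GF" = 1, "GG" = 13.34, "GH" = 1, "GI" = -7.49, "GK" = -7.49, "GL" = 1, "GM" = 1, "GN" = -7.49,
  "GP" = 1, "GQ" = 1, "GR" = 1, "GS" = 1, "GT" = -7.49, "GV" = 1, "GW" = 13.34, "GY" = -7.49,
  "HA" = 1, "HC" = 1, "HD" = 1, "HE" = 1, "HF" = -9.37, "HG" = -9.37, "HH" = 1, "HI" = 44.94,
  "HK" = 24.68, "HL" = 1, "HM" = 1, "HN" = 24.68, "HP" = -1.88, "HQ" = 1, "HR" = 1, "HS" = 1,
  "HT" = -6.54, "HV" = 1, "HW" = -1.88, "HY" = 44.94, "IA" = 1, "IC" = 1, "ID" = 1, "IE" = 44.94,
  "IF" = 1, "IG" = 1, "IH" = 13.34, "II" = 1, "IK" = -7.49, "IL" = 20.26, "IM" = 1, "IN" = 1,
  "IP" = -1.88, "IQ" = 1, "IR" = 1, "IS" = 1, "IT" = 1, "IV" = -7.49, "IW" = 1, "IY" = 1,
  "KA" = 1, "KC" = 1, "KD" = 1, "KE" = 1, "KF" = 1, "KG" = -7.49, "KH" = 1, "KI" = -7.49,
  "KK" = 1, "KL" = -7.49, "KM" = 33.6, "KN" = 1, "KP" = -6.54, "KQ" = 24.64, "KR" = 33.6, "KS" = 1,
  "KT" = 1, "KV" = -7.49, "KW" = 1, "KY" = 1, "LA" = 1, "LC" = 1, "LD" = 1, "LE" = 1,
  "LF" = 1, "LG" = 1, "LH" = 1, "LI" = 1, "LK" = -7.49, "LL" = 1, "LM" = 1, "LN" = 1,
  "LP" = 20.26, "LQ" = 33.6, "LR" = 20.26, "LS" = 1, "LT" = 1, "LV" = 1, "LW" = 24.68, "LY" = 1,
  "MA" = 13.34, "MC" = 1, "MD" = 1, "ME" = 1, "MF" = 1, "MG" = 1, "MH" = 58.28, "MI" = 1,
  "MK" = 1, "ML" = 1, "MM" = -1.88, "MN" = 1, "MP" = 44.94, "MQ" = -6.54, "MR" = -6.54, "MS" = 44.94,
  "MT" = -1.88, "MV" = 1, "MW" = 1, "MY" = 24.68, "NA" = 1, "NC" = -1.88, "ND" = 1, "NE" = 1,
  "NF" = -14.03, "NG" = -14.03, "NH" = 1, "NI" = 44.94, "NK" = 24.68, "NL" = 1, "NM" = 1, "NN" = 1,
  "NP" = -1.88, "NQ" = -6.54, "NR" = 1, "NS" = 1, "NT" = -7.49, "NV" = 1, "NW" = -9.37, "NY" = 1,
  "PA" = 20.26, "PC" = -6.54, "PD" = -6.54, "PE" = 18.38, "PF" = 20.26, "PG" = 1, "PH" = 1, "PI" = 1,
  "PK" = 1, "PL" = 1, "PM" = -6.54, "PN" = 1, "PP" = 20.26, "PQ" = 20.26, "PR" = -6.54, "PS" = 20.26,
  "PT" = 1, "PV" = 20.26, "PW" = -1.88, "PY" = 1, "QA" = 1, "QC" = -6.54, "QD" = 20.26, "QE" = 20.26,
  "QF" = -6.54, "QG" = 1, "QH" = 1, "QI" = 1, "QK" = 1, "QL" = 1, "QM" = 1, "QN" = 1,
  "QP" = 20.26, "QQ" = 20.26, "QR" = 1, "QS" = 44.94, "QT" = 1, "QV" = -6.54, "QW" = 1, "QY" = -6.54,
  "RA" = 1, "RC" = 1, "RD" = 1, "RE" = 1, "RF" = 1, "RG" = -7.49, "RH" = 20.26, "RI" = 1,
  "RK" = 1, "RL" = 1, "RM" = 1, "RN" = 13.34, "RP" = 20.26, "RQ" = 20.26, "RR" = 58.28, "RS" = 44.94,
  "RT" = 1, "RV" = 1, "RW" = 58.28, "RY" = -6.54, "SA" = 1, "SC" = 33.6, "SD" = 1, "SE" = 20.26,
  "SF" = 1, "SG" = 1, "SH" = 1, "SI" = 1, "SK" = 1, "SL" = 1, "SM" = 1, "SN" = 1,
  "SP" = 44.94, "SQ" = 20.26, "SR" = 20.26, "SS" = 20.26, "ST" = 1, "SV" = 1, "SW" = 1, "SY" = 1,
  "TA" = 1, "TC" = 1, "TD" = 1, "TE" = 20.26, "TF" = 13.34, "TG" = -7.49, "TH" = 1, "TI" = 1,
  "TK" = 1, "TL" = 1, "TM" = 1, "TN" = -14.03, "TP" = 1, "TQ" = -6.54, "TR" = 1, "TS" = 1,
  "TT" = 1, "TV" = 1, "TW" = -14.03, "TY" = 1, "VA" = 1, "VC" = 1, "VD" = -14.03, "VE" = 1,
  "VF" = 1, "VG" = -7.49, "VH" = 1, "VI" = 1, "VK" = -1.88, "VL" = 1, "VM" = 1, "VN" = 1,
  "VP" = 20.26, "VQ" = 1, "VR" = 1, "VS" = 1, "VT" = -7.49, "VV" = 1, "VW" = 1, "VY" = -6.54,
  "WA" = -14.03, "WC" = 1, "WD" = 1, "WE" = 1, "WF" = 1, "WG" = -9.37, "WH" = 24.68, "WI" = 1,
  "WK" = 1, "WL" = 13.34, "WM" = 24.68, "WN" = 13.34, "WP" = 1, "WQ" = 1, "WR" = 1, "WS" = 1,
  "WT" = -14.03, "WV" = -7.49, "WW" = 1, "WY" = 1, "YA" = 24.68, "YC" = 1, "YD" = 24.68, "YE" = -6.54,
  "YF" = 1, "YG" = -7.49, "YH" = 13.34, "YI" = 1, "YK" = 1, "YL" = 1, "YM" = 44.94, "YN" = 1,
  "YP" = 13.34, "YQ" = 1, "YR" = -15.91, "YS" = 1, "YT" = -7.49, "YV" = 1, "YW" = -9.37, "YY" = 13.34
)

oracle_instability <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  dips <- paste0(res[-L], res[-1])
  (10 / L) * sum(DIWV_ORACLE[dips])
}
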
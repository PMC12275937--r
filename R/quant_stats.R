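# Label-free quantitative downstream: total-abundance normalization,
# low-abundance missing-value imputation, paired tumor/normal fold change,
# differential calling, grade-trend profiles and per-SEP ROC AUC.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Normalize on total peptide abundance
#'
#' Each sample column is scaled so that its total of present (non-missing)
#' intensities equals the median of all column totals; missing entries remain
#' missing and within-column ratios are preserved. Idempotent.
#'
#' @param q A `quant_matrix`.
#' @return Normalized `quant_matrix`.
#' @export
normalize_total_abundance <- function(q) {
  totals <- colSums(q$values, na.rm = TRUE)
  if (any(totals == 0) || any(colSums(!is.na(q$values)) == 0))
    stop("column(s) with no present values: ",
         paste(colnames(q$values)[totals == 0], collapse = ", "))
  target <- stats::median(totals)
  q$values <- sweep(q$values, 2L, target / totals, `*`)
  q
}

#' Impute missing values by replicate-based low-abundance resampling
#'
#' Each missing entry is replaced by a value drawn uniformly at random from
#' that column's present values at or below its 5th percentile, emulating
#' stochastic dropout of low-abundance ions. Columns with fewer than 20
#' present values fall back to the column minimum, with a warning.
#' Reproducible given `seed`.
#'
#' @param q A `quant_matrix` (normalize first).
#' @param seed Integer RNG seed (mandatory).
#' @param low_quantile Quantile bounding the low-abundance pool (default 0.05).
#' @return `quant_matrix` without missing entries.
#' @export
impute_low_abundance <- function(q, seed, low_quantile = 0.05) {
  if (missing(seed)) stop("an explicit integer seed is required")
  v <- q$values
  .with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- which(is.na(v[, j]))
      if (!length(miss)) next
      present <- v[!is.na(v[, j]), j]
      if (length(present) < 20L) {
        warning("column ", colnames(v)[j], " has <20 present values; ",
                "imputing with the column minimum")
        v[miss, j] <- min(present)
      } else {
        pool <- present[present <= stats::quantile(present, low_quantile)]
        v[miss, j] <- sample(pool, length(miss), replace = TRUE)
      }
    }
  })
  q$values <- v
  q
}

#' Per-patient tumor/normal fold change
#'
#' For every SEP and patient, the fold change is the SEP's abundance in the
#' tumor sample divided by that in the paired adjacent normal sample.
#'
#' @param q An imputed `quant_matrix` (no missing values).
#' @return data.frame with `accession`, `patient_id`, `fc`, `log2fc`.
#' @export
pairwise_fold_change <- function(q) {
  if (anyNA(q$values)) stop("matrix contains missing values; impute first")
  s <- q$samples
  patients <- unique(s$patient_id)
  tum <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$tissue == "tumor"], "")
  nor <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$tissue == "normal"], "")
  if (any(q$values[, nor] == 0)) stop("zero normal intensity; cannot form ratio")
  fc <- q$values[, tum, drop = FALSE] / q$values[, nor, drop = FALSE]
  data.frame(accession = rep(rownames(fc), times = length(patients)),
             patient_id = rep(patients, each = nrow(fc)),
             fc = as.vector(fc), log2fc = as.vector(log2(fc)),
             stringsAsFactors = FALSE)
}

#' Differential expression calls between tumor and normal
#'
#' Per SEP, a two-sided paired t-test on log2 intensities across patients;
#' Benjamini-Hochberg q-values are reported, and the up/down call uses the
#' raw p-value and mean log2 fold-change thresholds (`p <= alpha` and
#' `|mean log2FC| >= lfc_min`).
#'
#' @param q An imputed, normalized `quant_matrix`.
#' @param alpha p-value threshold (default 0.05).
#' @param lfc_min Absolute mean log2 fold-change threshold (default 1).
#' @return data.frame with `accession`, `mean_log2fc`, `p_value`, `q_value`,
#'   `call` (`up`/`down`/`stable`).
#' @export
differential_call <- function(q, alpha = 0.05, lfc_min = 1) {
  if (anyNA(q$values)) stop("matrix contains missing values; impute first")
  s <- q$samples
  patients <- unique(s$patient_id)
  if (length(patients) < 3L) {
    warning("fewer than 3 pairs; no differential calls possible")
    return(data.frame(accession = character(0), mean_log2fc = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      call = character(0)))
  }
  tum <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$tissue == "tumor"], "")
  nor <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$tissue == "normal"], "")
  lt <- log2(q$values[, tum, drop = FALSE])
  ln <- log2(q$values[, nor, drop = FALSE])
  d <- lt - ln
  mean_lfc <- rowMeans(d)
  pv <- apply(d, 1L, function(x) {
    if (stats::sd(x) == 0) return(if (all(x == 0)) 1 else 0)
    stats::t.test(x)$p.value
  })
  call <- ifelse(pv <= alpha & mean_lfc >= lfc_min, "up",
                 ifelse(pv <= alpha & mean_lfc <= -lfc_min, "down", "stable"))
  data.frame(accession = rownames(q$values), mean_log2fc = mean_lfc,
             p_value = pv, q_value = stats::p.adjust(pv, "BH"),
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}

#' Grade-trend profiles from per-patient fold changes
#'
#' Per SEP, the mean log2 fold change within each tumor grade (ordered
#' II < III < IV), then row-standardized (mean 0, sd 1) for clustering.
#' Constant profiles (sd 0) are dropped with a warning.
#'
#' @param fcs Fold-change records from [pairwise_fold_change()].
#' @param samples The samples data.frame of the `quant_matrix`.
#' @param grades Grade order (default `c("II", "III", "IV")`).
#' @return Numeric SEP x grade matrix of standardized profiles. The raw
#'   (unstandardized) profiles are attached as attribute `"raw"`.
#' @export
grade_trend_profiles <- function(fcs, samples, grades = c("II", "III", "IV")) {
  tum <- samples[samples$tissue == "tumor", , drop = FALSE]
  pg <- tum$grade[match(fcs$patient_id, tum$patient_id)]
  if (!all(grades %in% pg)) stop("every grade must have at least one patient")
  prof <- vapply(grades, function(g)
    tapply(fcs$log2fc[pg == g], fcs$accession[pg == g], mean),
    numeric(length(unique(fcs$accession))))
  prof <- prof[order(rownames(prof)), , drop = FALSE]
  sds <- apply(prof, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) dropped before standardization")
    prof <- prof[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  std <- (prof - rowMeans(prof)) / sds
  attr(std, "raw") <- prof
  std
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with fuzzifier `m`: alternating updates of cluster
#' centers and memberships minimizing `sum_ik u_ik^m * ||x_i - c_k||^2`.
#' Membership rows sum to 1; the objective is non-increasing per iteration;
#' centers are initialized from `c` randomly chosen distinct rows (seeded).
#'
#' @param profiles Numeric item x feature matrix (row-standardized profiles
#'   for grade-trend clustering).
#' @param c Number of clusters (>= 2; default 8).
#' @param m Fuzzifier (> 1; default 2).
#' @param seed Integer RNG seed for center initialization.
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Iteration cap.
#' @return A `fuzzy_clusters` list: `centers` (c x features), `membership`
#'   (items x c), `hard` (named integer vector of max-membership clusters),
#'   `objective` (per-iteration trajectory), `m`, `iterations`.
#' @export
fuzzy_cmeans <- function(profiles, c = 8L, m = 2, seed = 1L,
                         tol = 1e-6, max_iter = 1000L) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (c < 2L) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (n < c) stop("fewer rows than clusters")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
    n <- nrow(x)
  }
  centers <- .with_seed(seed, x[sample.int(n, c), , drop = FALSE])
  dist2 <- function(ctr) {
    d <- outer(rowSums(x^2), rep(1, nrow(ctr))) +
      outer(rep(1, n), rowSums(ctr^2)) - 2 * x %*% t(ctr)
    pmax(d, 0)
  }
  obj <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- dist2(centers)
    # membership update; items coincident with a center get full membership
    u <- matrix(0, n, c)
    zero <- d2 < 1e-12
    anyzero <- rowSums(zero) > 0
    pw <- d2[!anyzero, , drop = FALSE]^(-1 / (m - 1))
    u[!anyzero, ] <- pw / rowSums(pw)
    u[anyzero, ] <- zero[anyzero, , drop = FALSE] /
      rowSums(zero[anyzero, , drop = FALSE])
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    obj <- c(obj, sum(um * dist2(centers)))
    if (it > 1L && abs(obj[it - 1L] - obj[it]) < tol) break
  }
  hard <- apply(u, 1L, which.max)
  names(hard) <- rownames(x)
  rownames(u) <- rownames(x)
  structure(list(centers = centers, membership = u, hard = hard,
                 objective = obj, m = m, c = c, iterations = length(obj)),
            class = "fuzzy_clusters")
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney U statistic,
#' `AUC = U / (n1 * n2)` with ties credited 0.5: the probability that a
#' randomly chosen positive outscores a randomly chosen negative.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or coercible) vector, `TRUE` = positive class.
#' @return List with `auc`, `n1` (positives), `n2` (negatives).
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0L || n2 == 0L) stop("both label classes must be present")
  r <- rank(scores)   # midranks handle ties
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  list(auc = u / (n1 * n2), n1 = n1, n2 = n2)
}

#' Per-SEP AUC over a grade contrast
#'
#' Scores each patient by the SEP's log2 tumor/normal fold change and
#' computes the Mann-Whitney AUC for a binary grade contrast (default:
#' grade II versus grades III and IV pooled, higher grades as positives).
#'
#' @param fcs Fold-change records from [pairwise_fold_change()].
#' @param samples Samples data.frame.
#' @param contrast `"II_vs_III+IV"` or `"II_vs_IV"`.
#' @return data.frame with `accession`, `auc`, `n1`, `n2`.
#' @export
auc_by_grade <- function(fcs, samples, contrast = c("II_vs_III+IV", "II_vs_IV")) {
  contrast <- match.arg(contrast)
  tum <- samples[samples$tissue == "tumor", , drop = FALSE]
  pg <- tum$grade[match(fcs$patient_id, tum$patient_id)]
  keep <- if (contrast == "II_vs_IV") pg %in% c("II", "IV") else TRUE
  fcs <- fcs[keep, , drop = FALSE]
  pg <- pg[keep]
  pos <- pg != "II"
  accs <- sort(unique(fcs$accession))
  rows <- lapply(accs, function(a) {
    i <- fcs$accession == a
    r <- auc_mann_whitney(fcs$log2fc[i], pos[i])
    data.frame(accession = a, auc = r$auc, n1 = r$n1, n2 = r$n2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
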
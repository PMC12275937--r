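mk_quant <- function(vals, grades = NULL) {
  np <- ncol(vals) / 2
  patients <- sprintf("P%02d", seq_len(np))
  colnames(vals) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("S%03d", seq_len(nrow(vals)))
  if (is.null(grades)) grades <- rep("II", np)
  quant_matrix(vals, data.frame(sample_id = colnames(vals),
                                patient_id = rep(patients, 2),
                                tissue = rep(c("tumor", "normal"), each = np),
                                grade = rep(grades, 2),
                                stringsAsFactors = FALSE))
}

test_that("normalization equalizes column totals at the median and is idempotent", {
  v <- matrix(c(10, 30, 60, 30, 90, 180), nrow = 3)  # totals 100, 300
  q <- mk_quant(v)
  qn <- normalize_total_abundance(q)
  expect_equal(unname(colSums(qn$values)), c(200, 200))
  # within-column ratios preserved
  expect_equal(qn$values[1, 1] / qn$values[2, 1], v[1, 1] / v[2, 1])
  # idempotent / fixed point on equal totals
  qnn <- normalize_total_abundance(qn)
  expect_equal(qnn$values, qn$values)
})

test_that("imputation draws from the low-abundance pool, deterministically", {
  set.seed(61)
  v <- matrix(2^rnorm(100 * 6, 20, 2), 100, 6)
  v[sample(length(v), 60)] <- NA
  q <- mk_quant(v)
  qi <- impute_low_abundance(q, seed = 9)
  expect_false(anyNA(qi$values))
  for (j in seq_len(ncol(v))) {
    present <- v[!is.na(v[, j]), j]
    bound <- quantile(present, 0.05)
    imputed <- qi$values[is.na(v[, j]), j]
    expect_true(all(imputed <= bound + 1e-12))
  }
  # observed entries unchanged; same seed byte-identical; other seed differs
  expect_identical(qi$values[!is.na(v)], v[!is.na(v)])
  expect_identical(impute_low_abundance(q, seed = 9)$values, qi$values)
  expect_false(identical(impute_low_abundance(q, seed = 10)$values, qi$values))
  # no missing entries: no-op
  expect_identical(impute_low_abundance(qi, seed = 1)$values, qi$values)
  # sparse column falls back to the column minimum with a warning
  v2 <- matrix(2^rnorm(10 * 4, 20, 2), 10, 4); v2[1, 1] <- NA
  expect_warning(qs <- impute_low_abundance(mk_quant(v2), seed = 3), "<20 present")
  expect_equal(qs$values[1, 1], min(v2[, 1], na.rm = TRUE))
})

test_that("per-patient fold change divides tumor by paired normal", {
  v <- matrix(c(200, 50, 400, 80, 100, 100, 100, 40), nrow = 2)
  q <- mk_quant(v)
  fcs <- pairwise_fold_change(q)
  expect_equal(nrow(fcs), 2 * 2)
  r11 <- fcs[fcs$accession == "S001" & fcs$patient_id == "P01", ]
  expect_equal(r11$fc, 2); expect_equal(r11$log2fc, 1)
  r22 <- fcs[fcs$accession == "S002" & fcs$patient_id == "P02", ]
  expect_equal(r22$fc, 2)  # 80/40
  expect_error(pairwise_fold_change(mk_quant(matrix(c(1, NA, 1, 1), 1))),
               "impute first")
})

test_that("differential calls recover a planted shift and stay quiet on nulls", {
  set.seed(62)
  np <- 18; ns <- 60
  base <- matrix(2^rnorm(ns * np, 20, 0.5), ns, np)
  shift <- c(rep(4, 20), rep(1, 40))  # first 20 SEPs: +2 log2 units
  v <- cbind(base * shift, matrix(2^rnorm(ns * np, 20, 0.5), ns, np))
  # rebuild paired structure: tumor = base*shift, normal fresh draws
  q <- mk_quant(v)
  de <- differential_call(impute_low_abundance(q, seed = 1))
  expect_true(mean(de$call[1:20] == "up") > 0.9)
  expect_true(mean(de$call[21:60] == "stable") > 0.8)
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  # identical tumor/normal columns: p in null territory, call stable
  same <- matrix(2^rnorm(30, 20, 1), 10, 3)
  q0 <- mk_quant(cbind(same, same))  # 3 patients, tumor == normal
  de0 <- differential_call(q0)
  expect_equal(nrow(de0), 10L)
  expect_true(all(de0$p_value == 1))
  expect_true(all(de0$call == "stable"))
})

test_that("the estimated effect concentrates around a planted 2-log2 shift", {
  # 50 planted SEPs, noise sd 0.5 on the paired difference, 18 pairs
  set.seed(69)
  np <- 18; ns <- 200
  normal <- matrix(2^rnorm(ns * np, 20, 2), ns, np)
  shift <- matrix(0, ns, np); shift[1:50, ] <- 2
  tumor <- normal * 2^(shift + matrix(rnorm(ns * np, 0, 0.5), ns, np))
  de <- differential_call(mk_quant(cbind(tumor, normal)))
  bound <- 3 * 0.5 / sqrt(np)
  expect_gte(mean(abs(de$mean_log2fc[1:50] - 2) < bound), 0.95)
  expect_gt(mean(de$call[1:50] == "up"), 0.9)
})

test_that("pairing invariance: permuting patient order leaves results unchanged", {
  set.seed(63)
  v <- matrix(2^rnorm(30 * 8, 20, 1), 30, 8)
  q <- mk_quant(v)
  de1 <- differential_call(q)
  perm <- c(3, 1, 4, 2)
  q2 <- quant_matrix(q$values[, c(perm, perm + 4)],
                     q$samples[c(perm, perm + 4), ])
  de2 <- differential_call(q2)
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$mean_log2fc, de2$mean_log2fc)
})

test_that("grade trend profiles are grade means, standardized, monotone-preserving", {
  grades <- c(rep("II", 4), rep("III", 3), rep("IV", 3))
  np <- 10
  fcs <- data.frame(accession = rep(c("A1", "A2"), each = np),
                    patient_id = rep(sprintf("P%02d", 1:np), 2),
                    fc = 1,
                    log2fc = c(ifelse(grades == "II", -1, ifelse(grades == "III", 0, 1)),
                               rep(0.5, np)))
  samples <- data.frame(sample_id = paste0(sprintf("P%02d", 1:np), "_T"),
                        patient_id = sprintf("P%02d", 1:np),
                        tissue = "tumor", grade = grades)
  expect_warning(prof <- grade_trend_profiles(fcs, samples), "constant")
  expect_equal(rownames(prof), "A1")           # constant A2 dropped
  expect_true(all(diff(prof["A1", ]) > 0))     # monotone preserved
  expect_equal(mean(prof["A1", ]), 0)
  expect_equal(sd(prof["A1", ]), 1)
  raw <- attr(prof, "raw")
  expect_equal(unname(raw["A1", ]), c(-1, 0, 1))
})

test_that("fuzzy c-means memberships are row-stochastic with monotone objective", {
  set.seed(64)
  x <- rbind(matrix(rnorm(40 * 3, mean = rep(c(-1, 0, 1), each = 40), sd = 0.2), 40, 3),
             matrix(rnorm(40 * 3, mean = rep(c(1, 0, -1), each = 40), sd = 0.2), 40, 3))
  x <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  rownames(x) <- sprintf("S%03d", 1:80)
  cl <- fuzzy_cmeans(x, c = 2, m = 2, seed = 5)
  expect_equal(unname(rowSums(cl$membership)), rep(1, 80), tolerance = 1e-9)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  expect_true(all(diff(cl$objective) <= 1e-9))
  # planted two-group structure recovered exactly
  expect_equal(length(unique(cl$hard[1:40])), 1L)
  expect_equal(length(unique(cl$hard[41:80])), 1L)
  expect_false(cl$hard[1] == cl$hard[41])
  # seeded byte-reproducibility
  cl2 <- fuzzy_cmeans(x, c = 2, m = 2, seed = 5)
  expect_identical(cl$membership, cl2$membership)
  expect_error(fuzzy_cmeans(x, c = 1), "c must be")
  expect_error(fuzzy_cmeans(x, c = 2, m = 1), "m must be")
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(65)
  x <- rbind(matrix(rnorm(30 * 3, -2, 0.3), 30, 3),
             matrix(rnorm(30 * 3, 2, 0.3), 30, 3))
  rownames(x) <- sprintf("S%03d", 1:60)
  cl <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1, tol = 1e-12, max_iter = 500)
  ref <- e1071::cmeans(x, centers = cl$centers, m = 2, iter.max = 500)
  ord <- if (sum((ref$centers[1, ] - cl$centers[1, ])^2) <
               sum((ref$centers[2, ] - cl$centers[1, ])^2)) 1:2 else 2:1
  expect_equal(unname(cl$centers), unname(ref$centers[ord, ]), tolerance = 1e-3)
  expect_equal(unname(cl$membership), unname(ref$membership[, ord]),
               tolerance = 1e-3)
})

test_that("AUC equals brute-force pair counting with midrank ties", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 10, 11, 12),
                                c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  set.seed(66)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(round(rnorm(n), 1))  # rounded to force ties
    r <- auc_mann_whitney(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels))
    expect_equal(r$auc + auc_mann_whitney(-scores, labels)$auc, 1.0)
  }
  expect_error(auc_mann_whitney(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both label")
})

test_that("AUC agrees with pROC and concentrates at 0.5 under label permutation", {
  set.seed(67)
  scores <- rnorm(400); labels <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  a <- auc_mann_whitney(scores, labels)$auc
  expect_true(abs(a - 0.5) < 0.1)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                 direction = "<"))))
})

test_that("per-SEP grade AUC separates planted trends in the default contrast", {
  cfg <- sim_config(seed = 68)
  qb <- simulate_quant(cfg, withr::local_tempdir())
  qi <- impute_low_abundance(normalize_total_abundance(qb$q), seed = 1)
  fcs <- pairwise_fold_change(qi)
  auc <- auc_by_grade(fcs, qi$samples)
  tru <- qb$truth
  m_up <- mean(auc$auc[auc$accession %in% tru$accession[tru$class == "trend_up"]])
  m_dn <- mean(auc$auc[auc$accession %in% tru$accession[tru$class == "trend_down"]])
  expect_gt(m_up, 0.5)
  expect_lt(m_dn, 0.5)
  expect_equal(unique(auc$n1), 9)  # grades III+IV
  expect_equal(unique(auc$n2), 9)  # grade II
  auc2 <- auc_by_grade(fcs, qi$samples, contrast = "II_vs_IV")
  expect_equal(unique(auc2$n1), 6)
})
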
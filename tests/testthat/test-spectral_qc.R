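# spectra built directly from ladder m/z values so the matched sets are
# known by construction

spec_from_mz <- function(mz, id = "fx", intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(1e4, length(mz))
  spectrum(id, 500, 2L, mz, intensity)
}

# a peptide whose ladder m/z values are mutually separated by > 0.05 Da,
# so planted peaks can never be attributed to another ion
separated_peptide <- function(len) {
  repeat {
    p <- random_peptide(len, len)
    l <- fragment_ladder(p, charges = 1L)
    if (all(diff(sort(c(l$b_mz[, 1], l$y_mz[, 1]))) > 0.05)) return(p)
  }
}

test_that("peak matching respects the tolerance boundary and nearest wins", {
  l <- fragment_ladder("ACDK", charges = 1L)
  target <- unname(l$b_mz[2, 1])
  m <- annotate_spectrum(l, spec_from_mz(target + 0.015), tol_da = 0.02)
  expect_true(2L %in% m$matched_b)
  m2 <- annotate_spectrum(l, spec_from_mz(target + 0.025), tol_da = 0.02)
  expect_false(2L %in% m2$matched_b)
  # two qualifying peaks: the nearer one is recorded
  m3 <- annotate_spectrum(l, spec_from_mz(c(target + 0.012, target - 0.004)),
                          tol_da = 0.02)
  expect_equal(m3$detail$obs_mz[m3$detail$series == "b" & m3$detail$index == 2],
               target - 0.004)
})

test_that("a spectrum containing the full ladder matches every ion", {
  set.seed(21)
  p <- random_peptide(8, 15)
  l <- fragment_ladder(p, charges = 1L)
  m <- annotate_spectrum(l, spec_from_mz(c(l$b_mz[, 1], l$y_mz[, 1])))
  expect_equal(m$matched_b, seq_len(nchar(p) - 1L))
  expect_equal(m$matched_y, seq_len(nchar(p) - 1L))
  expect_equal(ion_coverage(m), 1.0)
  # empty peak list is not an error
  m0 <- annotate_spectrum(l, spec_from_mz(numeric(0)))
  expect_length(m0$matched_b, 0L)
})

test_that("longest consecutive run never spans the b and y series", {
  mk <- function(b, y) structure(list(matched_b = b, matched_y = y, length = 10L),
                                 class = "ion_matches")
  expect_equal(longest_consecutive_run(mk(1:4, integer(0))), 4L)
  expect_equal(longest_consecutive_run(mk(c(1L, 3L, 5L), c(2L, 3L))), 2L)
  expect_equal(longest_consecutive_run(mk(integer(0), integer(0))), 0L)
})

test_that("ion coverage counts each index once over 2(L-1) ions", {
  mk <- function(b, y, L) structure(list(matched_b = b, matched_y = y, length = L),
                                    class = "ion_matches")
  expect_equal(ion_coverage(mk(c(1L, 2L), 1L, 6L)), 0.30)
  expect_equal(ion_coverage(mk(1:4, 1:4, 11L)), 0.40)
  expect_error(ion_coverage(mk(integer(0), integer(0), 1L)), ">= 2")
})

test_that("criteria boundary fixtures: run 3 vs 4, coverage 0.39 vs 0.40", {
  set.seed(22)
  # run boundary: peptide of length 21, only b1..b3 vs b1..b4 planted
  p <- separated_peptide(21)
  l <- fragment_ladder(p, charges = 1L)
  c3 <- evaluate_spectrum_criteria(p, spec_from_mz(l$b_mz[1:3, 1]))
  c4 <- evaluate_spectrum_criteria(p, spec_from_mz(l$b_mz[1:4, 1]))
  expect_equal(c3$longest_run, 3L); expect_false(c3$pass_run)
  expect_equal(c4$longest_run, 4L); expect_true(c4$pass_run)
  # coverage boundary: length 51 gives 100 ions; 39 vs 40 planted
  p2 <- separated_peptide(51)
  l2 <- fragment_ladder(p2, charges = 1L)
  c39 <- evaluate_spectrum_criteria(p2, spec_from_mz(c(l2$b_mz[1:20, 1],
                                                       l2$y_mz[1:19, 1])))
  c40 <- evaluate_spectrum_criteria(p2, spec_from_mz(c(l2$b_mz[1:20, 1],
                                                       l2$y_mz[1:20, 1])))
  expect_equal(c39$ion_coverage, 0.39); expect_false(c39$pass_coverage)
  expect_equal(c40$ion_coverage, 0.40); expect_true(c40$pass_coverage)
})

test_that("pure-noise and alternating-ion fixtures give the designed flags", {
  set.seed(23)
  p <- separated_peptide(11)
  l <- fragment_ladder(p, charges = 1L)
  noise <- spec_from_mz(sort(c(l$b_mz[, 1], l$y_mz[, 1])) + 0.5)
  cn <- evaluate_spectrum_criteria(p, noise)
  expect_equal(cn$ion_coverage, 0)
  expect_false(cn$pass_run); expect_false(cn$pass_coverage)
  # alternating b and y ions: 50% coverage but no run of 2
  alt <- spec_from_mz(c(l$b_mz[seq(1, 9, 2), 1], l$y_mz[seq(1, 9, 2), 1]))
  ca <- evaluate_spectrum_criteria(p, alt)
  expect_equal(ca$ion_coverage, 0.5)
  expect_true(ca$pass_coverage); expect_false(ca$pass_run)
  expect_error(evaluate_spectrum_criteria(p, noise, spectrum_id = "other"),
               "does not match")
})

test_that("matched sets equal a brute-force all-pairs scan and are monotone in tolerance", {
  set.seed(24)
  for (i in 1:60) {
    p <- random_peptide(6, 18)
    s <- simulate_spectrum(p, completeness = runif(1, 0.2, 1),
                           n_noise = sample(0:10, 1), jitter_sd = 0.005,
                           seed = i)
    l <- fragment_ladder(p, charges = 1L)
    m <- annotate_spectrum(l, s, tol_da = 0.02)
    expect_equal(m$matched_b, oracle_matched_indices(l$b_mz, s$mz, 0.02))
    expect_equal(m$matched_y, oracle_matched_indices(l$y_mz, s$mz, 0.02))
    m_tight <- annotate_spectrum(l, s, tol_da = 0.005)
    expect_true(length(m_tight$matched_b) + length(m_tight$matched_y) <=
                  length(m$matched_b) + length(m$matched_y))
  }
})

test_that("spectral similarity is 1 for identical, 0 for disjoint, scale-invariant", {
  set.seed(25)
  p <- random_peptide(8, 12)
  a <- simulate_spectrum(p, completeness = 0.9, n_noise = 3, seed = 1)
  expect_equal(spectral_similarity(a, a), 1.0)
  b <- spectrum("b", a$precursor_mz, 2L, a$mz + 1.0, a$intensity)
  expect_equal(spectral_similarity(a, b), 0.0)
  c10 <- spectrum("c", a$precursor_mz, 2L, a$mz, a$intensity * 10)
  expect_equal(spectral_similarity(a, c10), 1.0)
  # symmetry
  d <- simulate_spectrum(p, completeness = 0.7, n_noise = 5, seed = 2)
  expect_equal(spectral_similarity(a, d), spectral_similarity(d, a),
               tolerance = 1e-9)
  expect_error(spectral_similarity(a, spec_from_mz(numeric(0))), "non-empty")
})
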
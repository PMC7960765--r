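# EIC extraction, peak integration, stoichiometry quantification and the
# printed-table statistics

hinge <- "HYTNPSQDVTVPCPVPSTPPTPSPSTPPTPSPSCCHPR"

make_scans <- function(rt, mzs, ints) {
  scan_set(lapply(seq_along(rt), function(i)
    list(rt = rt[i], peaks = data.frame(mz = mzs, intensity = ints[[i]]))))
}

test_that("EIC window captures exact peaks and excludes displaced ones", {
  rt <- c(1, 2, 3)
  scans <- make_scans(rt, 500, list(10, 20, 5))
  trace <- extract_eic(scans, 500, tolerance_ppm = 10)
  expect_equal(trace$intensity, c(10, 20, 5))
  # displaced by twice the tolerance: all-zero trace
  off <- 500 * (1 + 20e-6)
  expect_equal(extract_eic(scans, off, tolerance_ppm = 10)$intensity,
               c(0, 0, 0))
  expect_error(extract_eic(scans, 500, tolerance_ppm = 0), "tolerance")
})

test_that("co-eluting species 1 m/z apart give independent traces", {
  rt <- seq(0, 1, by = 0.1)
  mzs <- c(1000, 1001)
  scans <- scan_set(lapply(rt, function(t)
    list(rt = t, peaks = data.frame(mz = mzs, intensity = c(3, 7)))))
  e1 <- extract_eic(scans, 1000, 10)
  e2 <- extract_eic(scans, 1001, 10)
  expect_true(all(e1$intensity == 3))
  expect_true(all(e2$intensity == 7))
})

test_that("trapezoidal integration: rectangle, Gaussian, degenerate window", {
  rt <- seq(0, 2, by = 0.01)
  const <- structure(data.frame(rt = rt, intensity = 5),
                     class = c("eic", "data.frame"))
  expect_equal(integrate_peak(const, c(0, 2)), 10, tolerance = 1e-12)
  gauss <- structure(
    data.frame(rt = rt, intensity = 42 * dnorm(rt, 1, 0.05)),
    class = c("eic", "data.frame"))
  expect_equal(integrate_peak(gauss, c(0, 2)), 42, tolerance = 0.001 * 42)
  expect_equal(integrate_peak(gauss, c(1, 1)), 0)
  expect_error(integrate_peak(gauss, c(2, 1)), "inverted")
})

test_that("noiseless adduct-free runs recover the configured stoichiometry", {
  f <- c(0.263, 0.279, 0.239, 0.160, 0.048, 0.011, 0.001); f <- f / sum(f)
  scans <- simulate_lcms_run(ground_truth(hinge, f, seed = 21))
  d <- quantify_stoichiometry(scans, hinge, 6)
  expect_true(max(abs(d$fractions_percent / 100 - f)) < 1e-3)
  dm <- quantify_stoichiometry_monoiso(scans, hinge, 6)
  expect_true(max(abs(dm$fractions_percent / 100 - f)) < 1e-3)
  # the two modes agree when no adduct interferes
  expect_true(max(abs(d$fractions_percent - dm$fractions_percent)) < 1)
})

test_that("recovery holds for random stoichiometry vectors", {
  set.seed(31)
  for (rep in 1:5) {
    f <- rexp(7); f <- f / sum(f)
    scans <- simulate_lcms_run(ground_truth(hinge, f, seed = 100 + rep))
    d <- quantify_stoichiometry(scans, hinge, 6)
    expect_true(max(abs(d$fractions_percent / 100 - f)) < 1e-3)
  }
})

test_that("monoisotopic fallback beats 4-peak mode under adduct load", {
  f <- c(0.263, 0.279, 0.239, 0.160, 0.048, 0.011, 0.001); f <- f / sum(f)
  for (s in 1:10) {
    scans <- simulate_lcms_run(ground_truth(hinge, f, adduct_fraction = 0.2,
                                            noise_cv = 0.02, seed = 200 + s))
    err4 <- max(abs(quantify_stoichiometry(scans, hinge, 6)$fractions_percent /
                      100 - f))
    err1 <- max(abs(quantify_stoichiometry_monoiso(scans, hinge, 6)$fractions_percent /
                      100 - f))
    expect_lt(err1, err4)
  }
})

test_that("empty and single-species quantifications behave", {
  rt <- c(1, 2)
  empty <- make_scans(rt, 100, list(1, 1))
  expect_error(quantify_stoichiometry(empty, hinge, 6), "empty quantification")
  expect_error(quantify_stoichiometry(empty, hinge, 20), "max_ox")
})

test_that("adduct-overlap detection reduces to the three mass constants", {
  hits <- detect_adduct_overlap(hinge, 6, charges = 2L, tolerance_ppm = 10)
  expect_equal(hits$n_ox, 1:6)
  expect_equal(hits$delta_mz,
               rep(abs(17.026549 - 15.994915 - 1.0033548378) / 2, 6),
               tolerance = 1e-9)
  # 1 ppm at ~2070 m/z is ~0.002: too narrow to merge the 0.014 separation
  expect_equal(nrow(detect_adduct_overlap(hinge, 6, charges = 2L,
                                          tolerance_ppm = 1)), 0)
})

test_that("average Hyp count reproduces the printed table statistics", {
  printed <- c(1.49, 2.75, 1.35, 1.85, 1.88, 1.26, 1.32, 1.33, 1.57, 1.17, 0.84)
  computed <- vapply(published_stoich_rows, average_hyp, numeric(1))
  expect_equal(unname(computed), printed)
  expect_equal(average_hyp(c(100, 0, 0, 0, 0, 0, 0)), 0)
  expect_error(average_hyp(c(-1, 101)), "non-negative")
})

test_that("percentages are used as printed, without renormalization", {
  # this row sums to 99.9; renormalizing would give 2.76, printed is 2.75
  expect_equal(sum(published_stoich_rows$p4h1_over), 99.9)
  expect_equal(average_hyp(published_stoich_rows$p4h1_over), 2.75)
})

test_that("percent change rounds half away from zero on unrounded averages", {
  ctrl <- sum(0:6 * published_stoich_rows$ppt2m_ctrl) / 100
  avs <- vapply(published_stoich_rows[c("ppt2m_p4h1r", "ppt2m_p4h10r", "ppt2m_both")],
                function(f) sum(0:6 * f) / 100, numeric(1))
  expect_equal(unname(vapply(avs, percent_change, integer(1),
                             av_control = ctrl)),
               c(119L, 88L, 64L))
  expect_equal(percent_change(1.5, 1.5), 100L)
  expect_error(percent_change(1, 0), "> 0")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(1.165, 2), 1.17)
  expect_equal(round_half_away(-1.165, 2), -1.17)
  expect_equal(round_half_away(63.65, 0), 64)
  expect_equal(round_half_away(2.753, 2), 2.75)
})

test_that("hyp distributions normalize and bound the average", {
  set.seed(17)
  for (rep in 1:10) {
    f <- rexp(7); f <- 100 * f / sum(f)
    d <- hyp_distribution(hinge, f)
    expect_equal(sum(d$fractions_percent) / 100, 1, tolerance = 1e-6)
    expect_gte(d$average_hyp_raw, 0)
    expect_lte(d$average_hyp_raw, 6)
  }
})
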
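# peptide chemistry: compositions, masses, m/z, envelopes, digestion,
# oxoform enumeration

test_that("elemental composition matches residue-formula convention", {
  g <- peptide_composition("G")
  expect_equal(unclass(g)[sort(names(g))],
               c(C = 2, H = 5, N = 1, O = 2))

  pp <- peptide_composition("PP")
  oracle <- oracle_composition("PP")
  expect_equal(unclass(pp)[sort(names(pp))], oracle[sort(names(oracle))])

  cam <- peptide_composition(
    peptidoform("C", mods = data.frame(position = 1,
                                       modification = "carbamidomethyl")))
  plain <- peptide_composition("C")
  expect_equal(unclass(composition_add(plain, c(C = 2, H = 3, N = 1, O = 1))),
               unclass(cam))
})

test_that("composition arithmetic is element-wise and never negative", {
  a <- elemental_composition(c(C = 2, H = 4))
  b <- elemental_composition(c(H = 1, O = 1))
  s <- composition_add(a, b)
  expect_equal(unclass(s)[c("C", "H", "O")], c(C = 2, H = 5, O = 1))
  expect_error(composition_add(a, c(O = 1), sign = -1), "negative")
  expect_error(elemental_composition(c(C = -1)), "non-negative")
})

test_that("unknown residues are reported with letter and position", {
  expect_error(peptidoform("AXG"), "X.*position 2")
})

test_that("monoisotopic masses agree with the atom-summation oracle", {
  is_pep <- "PTTTPITTTTTVTPTPTPTGTQTK"
  expect_equal(monoisotopic_mass(is_pep), oracle_mass(is_pep),
               tolerance = 1e-10)
  iga <- "VTVPVPSTPPTPSPSTPPTPSPS"
  expect_equal(monoisotopic_mass(iga), oracle_mass(iga), tolerance = 1e-10)
  expect_error(monoisotopic_mass(""), "non-empty")
})

test_that("modification mass shifts equal their composition deltas", {
  for (mod in MODIFICATIONS) {
    delta_mass <- sum(unclass(elemental_composition(mod$composition_delta)) *
                        .oracle_atom_mass[names(mod$composition_delta)])
    expect_equal(mod$mass_shift, delta_mass, tolerance = 1e-6)
  }
})

test_that("mass additivity holds for any peptide split", {
  set.seed(42)
  water <- 2 * 1.007825032 + 15.994914620
  for (rep in 1:20) {
    pep <- random_peptide(sample(4:30, 1))
    cut <- sample(seq_len(nchar(pep) - 1), 1)
    a <- substr(pep, 1, cut); b <- substr(pep, cut + 1, nchar(pep))
    expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b) - water,
                 monoisotopic_mass(pep), tolerance = 1e-9)
  }
})

test_that("mz follows the protonation formula and oxidation shift rule", {
  m <- 1000
  expect_equal(mz(m, 1), m + 1.007276467)
  ox <- MODIFICATIONS$oxidation$mass_shift
  for (z in 1:3)
    expect_equal(mz(m + ox, z) - mz(m, z), ox / z, tolerance = 1e-12)
  # strictly decreasing in charge for fixed mass
  expect_true(all(diff(mz(m, 1:6)) < 0))
  expect_error(mz(m, 0), "positive")
  expect_error(mz(m, -2), "positive")
  # ammonium adduct sits +17.026549/z above the protonated species
  expect_equal(mz(m, 2, AMMONIUM_ADDUCT_SHIFT) - mz(m, 2),
               17.026549 / 2)
})

test_that("single-carbon envelope reproduces natural 12C/13C abundances", {
  env <- isotope_distribution(c(C = 1), n_peaks = 2)
  expect_equal(env$abundance, c(0.9893, 0.0107))
  expect_equal(env$offset, c(0L, 1L))
})

test_that("envelopes are normalized and match the multinomial oracle", {
  # small compositions, exhaustively enumerable
  comps <- list(c(C = 3, H = 5, N = 1, O = 2),
                c(C = 6, H = 11, N = 1, O = 1, S = 1),
                c(C = 2, O = 3))
  for (comp in comps) {
    env <- isotope_distribution(elemental_composition(comp), n_peaks = 5)
    expect_equal(sum(env$abundance), 1, tolerance = 1e-12)
    expect_equal(env$abundance, oracle_envelope(comp, 5), tolerance = 1e-9)
  }
  # a full peptide-scale composition
  iga_comp <- unclass(peptide_composition("VTVPVPSTPPTPSPSTPPTPSPS"))
  env <- isotope_distribution(peptide_composition("VTVPVPSTPPTPSPSTPPTPSPS"),
                              n_peaks = 6)
  expect_equal(env$abundance, oracle_envelope(iga_comp, 6), tolerance = 1e-9)
  expect_error(isotope_distribution(elemental_composition(c(C = 1)), 0),
               "n_peaks")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("AKPR")$peptide, "AKPR")
  expect_equal(tryptic_digest("AKGR")$peptide, c("AK", "GR"))
  expect_setequal(tryptic_digest("AKGR", 1)$peptide, oracle_digest("AKGR", 1))
  # no cleavage site: whole sequence
  expect_equal(tryptic_digest("GGGG")$peptide, "GGGG")
})

test_that("digest fragments reconstruct the input and match the oracle", {
  set.seed(7)
  for (rep in 1:15) {
    pep <- random_peptide(sample(5:40, 1))
    d0 <- tryptic_digest(pep, 0)
    expect_identical(paste(d0$peptide, collapse = ""), pep)
    m <- sample(0:2, 1)
    expect_setequal(unique(tryptic_digest(pep, m)$peptide),
                    oracle_digest(pep, m))
  }
})

test_that("oxoform enumeration yields all combinations in order", {
  iga <- "VTVPVPSTPPTPSPSTPPTPSPS"
  sites <- c(9, 10, 12, 14, 17, 18, 20)
  forms <- enumerate_oxoforms(iga, sites, 2)
  expect_length(forms, choose(7, 2))
  placements <- t(vapply(forms, function(pf) pf$mods$position, integer(2)))
  expect_equal(placements, t(combn(as.integer(sites), 2)))  # lexicographic

  expect_length(enumerate_oxoforms(iga, sites, 0), 1)
  expect_identical(nrow(enumerate_oxoforms(iga, sites, 0)[[1]]$mods), 0L)
  expect_error(enumerate_oxoforms(iga, sites, 8), "between 0")
  expect_error(enumerate_oxoforms(iga, c(1, 9), 1), "proline")
})

test_that("peptidoform validation enforces allowed residues and positions", {
  expect_error(peptidoform("APA", mods = data.frame(position = 1,
                                                    modification = "oxidation")),
               "not allowed")
  expect_error(peptidoform("APA", mods = data.frame(position = 9,
                                                    modification = "oxidation")),
               "outside")
  expect_error(peptidoform("APA", mods = data.frame(
    position = c(2, 2), modification = c("oxidation", "oxidation"))),
    "one modification per position")
})

test_that("isotope table is exposed with normalized abundances", {
  tab <- isotope_table()
  expect_true(all(c("element", "nominal_offset", "mass", "abundance") %in%
                    names(tab)))
  sums <- tapply(tab$abundance, tab$element, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
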
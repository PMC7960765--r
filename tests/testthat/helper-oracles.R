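# Independent oracles for mass, envelope, fragment and digest computations.
# These deliberately use different data representations and algorithms than
# the package (formula strings, multinomial enumeration, regex scanning) so
# agreement is evidence, not tautology.

# residue formulas as strings, parsed on the fly
.oracle_formulas <- c(
  G = "C2H3N1O1", A = "C3H5N1O1", S = "C3H5N1O2", P = "C5H7N1O1",
  V = "C5H9N1O1", T = "C4H7N1O2", C = "C3H5N1O1S1", L = "C6H11N1O1",
  I = "C6H11N1O1", N = "C4H6N2O2", D = "C4H5N1O3", Q = "C5H8N2O2",
  K = "C6H12N2O1", E = "C5H7N1O3", M = "C5H9N1O1S1", H = "C6H7N3O1",
  F = "C9H9N1O1", R = "C6H12N4O1", Y = "C9H9N1O2", W = "C11H10N2O1"
)
.oracle_atom_mass <- c(H = 1.007825032, C = 12, N = 14.003074005,
                       O = 15.994914620, S = 31.972071174)

oracle_parse_formula <- function(s) {
  parts <- regmatches(s, gregexpr("([A-Z])([0-9]+)", s))[[1]]
  counts <- as.integer(sub("^[A-Z]", "", parts))
  names(counts) <- sub("[0-9]+$", "", parts)
  counts
}

# atom-by-atom summation over residues + water + modification deltas
oracle_composition <- function(sequence, mod_formulas = character()) {
  total <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  for (r in strsplit(sequence, "")[[1]]) {
    f <- oracle_parse_formula(.oracle_formulas[[r]])
    total[names(f)] <- total[names(f)] + f
  }
  for (mf in mod_formulas) {
    f <- oracle_parse_formula(mf)
    total[names(f)] <- total[names(f)] + f
  }
  total[total != 0]
}

oracle_mass <- function(sequence, mod_formulas = character()) {
  comp <- oracle_composition(sequence, mod_formulas)
  sum(comp * .oracle_atom_mass[names(comp)])
}

# per-element aggregated pattern by explicit multinomial enumeration over
# isotope count vectors, then cross-element combination via expand.grid
.oracle_isotopes <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

.oracle_element_pattern <- function(n_atoms, probs, max_offset) {
  k <- length(probs)
  # all count vectors (n_0..n_{k-1}) with sum n_atoms and offset <= max_offset
  grids <- lapply(seq_len(k - 1), function(i) 0:min(n_atoms, max_offset))
  combos <- if (k == 1) data.frame(row = 0) else do.call(expand.grid, grids)
  out <- numeric(max_offset + 1)
  for (r in seq_len(nrow(combos))) {
    heavy <- as.numeric(combos[r, , drop = TRUE])
    if (k == 1) heavy <- numeric(0)
    if (sum(heavy) > n_atoms) next
    offset <- sum(heavy * seq_along(heavy))
    if (offset > max_offset) next
    counts <- c(n_atoms - sum(heavy), heavy)
    out[offset + 1] <- out[offset + 1] + stats::dmultinom(counts, prob = probs)
  }
  out
}

oracle_envelope <- function(counts, n_peaks) {
  max_offset <- n_peaks + 7L
  pats <- lapply(names(counts), function(el)
    .oracle_element_pattern(counts[[el]], .oracle_isotopes[[el]], max_offset))
  # combine by enumerating joint per-element offsets
  offs <- lapply(pats, function(p) seq_along(p) - 1L)
  grid <- do.call(expand.grid, offs)
  total_off <- rowSums(grid)
  keep <- total_off <= max_offset
  probs <- rep(1, nrow(grid))
  for (j in seq_along(pats)) probs <- probs * pats[[j]][grid[[j]] + 1L]
  env <- vapply(0:max_offset, function(o) sum(probs[keep & total_off == o]),
                numeric(1))
  env <- env[seq_len(n_peaks)]
  env / sum(env)
}

# prefix/suffix fragment masses from the formula-string residue table
oracle_fragments <- function(sequence, ox_positions = integer(),
                             cam_positions = integer()) {
  res <- strsplit(sequence, "")[[1]]
  masses <- vapply(res, function(r) {
    f <- oracle_parse_formula(.oracle_formulas[[r]])
    sum(f * .oracle_atom_mass[names(f)])
  }, numeric(1))
  masses[ox_positions] <- masses[ox_positions] + 15.994915
  masses[cam_positions] <- masses[cam_positions] + 57.021464
  L <- length(masses)
  proton <- 1.007276467
  water <- 18.010564684
  list(
    b = vapply(1:(L - 1), function(i) sum(masses[1:i]) + proton, numeric(1)),
    y = vapply(1:(L - 1), function(j) sum(masses[(L - j + 1):L]) + water + proton,
               numeric(1))
  )
}

# brute-force digestion: regex-located cleavage points, adjacent-union
# enumeration
oracle_digest <- function(sequence, missed = 0) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts <- integer()
  for (i in seq_len(n - 1))
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cuts <- c(cuts, i)
  bounds <- c(0, cuts, n)
  frags <- character()
  for (i in 1:(length(bounds) - 1))
    for (j in i:min(i + missed, length(bounds) - 1))
      frags <- c(frags, substr(sequence, bounds[i] + 1, bounds[j + 1]))
  sort(unique(frags))
}

# shared fixture: published relative-quantification rows for the hinge
# peptide (percentages of species with 0..6 hydroxyprolines)
published_stoich_rows <- list(
  nb_iga1        = c(26.3, 27.9, 23.9, 16.0, 4.8, 1.1, 0.1),
  p4h1_over      = c(9.6, 12.5, 17.2, 25.4, 25.5, 8.0, 1.7),
  p4h4_over      = c(32.0, 28.4, 19.9, 13.7, 4.8, 1.2, 0.1),
  p4h9_over      = c(20.7, 23.5, 21.8, 20.9, 9.7, 2.9, 0.3),
  p4h10_over     = c(18.0, 23.1, 27.4, 19.6, 8.3, 3.1, 0.5),
  p4h10_rnai     = c(35.2, 31.0, 19.7, 6.6, 4.0, 1.9, 1.7),
  both_rnai      = c(31.5, 31.0, 20.5, 10.8, 4.2, 1.4, 0.7),
  ppt2m_ctrl     = c(32.2, 30.7, 18.8, 11.4, 5.2, 1.5, 0.3),
  ppt2m_p4h1r    = c(23.1, 30.5, 23.6, 14.4, 6.1, 1.9, 0.4),
  ppt2m_p4h10r   = c(36.9, 31.5, 17.1, 8.9, 4.1, 1.3, 0.2),
  ppt2m_both     = c(50.5, 27.0, 13.7, 6.0, 2.5, 0.4, 0.0)
)

# Michaelis-Menten parameters of the four recombinant enzymes (Km uM,
# vmax uM/min, endpoint reaction time min)
enzyme_params <- list(
  "Nb-P4H1"  = list(km = 8,    vmax = 0.03, reaction_time = 30),
  "Nb-P4H4"  = list(km = 1900, vmax = 0.1,  reaction_time = 30),
  "Nb-P4H9"  = list(km = 72,   vmax = 0.4,  reaction_time = 20),
  "Nb-P4H10" = list(km = 66,   vmax = 0.02, reaction_time = 20)
)

random_peptide <- function(len, alphabet = names(.oracle_formulas)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
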
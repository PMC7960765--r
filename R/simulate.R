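# Synthetic-data generators emulating Q-TOF LC-ESI-MS measurements: MS1 runs
# of oxidized peptidoform mixtures, singly charged b/y MS/MS spectra, and
# internal-standard endpoint kinetics assays. All generators are ground-truthed
# and reproducible from a seed.

#' Ground truth for a simulated LC-MS1 run
#'
#' Describes a mixture of 0..k-times oxidized forms of one peptide as it would
#' appear in a centroided LC-ESI-MS run: relative stoichiometry, charge-state
#' weights (doubly and triply charged ions dominate in practice), optional
#' ammonium-adduct signal, Gaussian chromatographic peaks with per-species
#' retention times, and multiplicative intensity noise.
#'
#' @param peptide Peptide sequence; cysteines are treated as
#'   carbamidomethylated (fixed modification).
#' @param fractions Numeric vector `f_0..f_k` of unit fractions summing to 1;
#'   `fractions[n+1]` is the abundance of the species with n hydroxyprolines.
#' @param charge_weights Named vector mapping charge to signal fraction;
#'   default `c("2" = 0.7, "3" = 0.3)`.
#' @param adduct_fraction Fraction of each species' signal appearing as the
#'   ammonium adduct \[M+NH4\]+ instead of \[M+H\]+ (default 0).
#' @param rt_centers Retention-time centers (min), one per species; default
#'   `1 + 0.25 * (0:k)` so species are chromatographically spread.
#' @param rt_width Gaussian chromatographic sigma in minutes (> 0).
#' @param noise_cv Coefficient of variation of multiplicative intensity noise.
#' @param total_signal Total integrated signal across all species.
#' @param mz_tolerance_ppm Instrument m/z tolerance recorded with the run.
#' @param n_iso Number of isotope peaks emitted per species (envelope
#'   coverage; default 10 captures essentially the whole envelope of a
#'   peptide-sized molecule).
#' @param seed Integer seed; identical configuration + seed gives identical
#'   output.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(peptide, fractions,
                         charge_weights = c("2" = 0.7, "3" = 0.3),
                         adduct_fraction = 0,
                         rt_centers = NULL,
                         rt_width = 0.02,
                         noise_cv = 0,
                         total_signal = 1e6,
                         mz_tolerance_ppm = 10,
                         n_iso = 10L,
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (rt_width <= 0) stop("rt_width must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (adduct_fraction < 0 || adduct_fraction > 1)
    stop("adduct_fraction must lie in [0, 1]")
  if (abs(sum(charge_weights) - 1) > 1e-9)
    stop("charge_weights must sum to 1")
  k <- length(fractions) - 1L
  if (k > length(proline_sites(peptide)))
    stop("more oxidized species than prolines in the peptide")
  if (is.null(rt_centers)) rt_centers <- 1 + 0.25 * (0:k)
  if (length(rt_centers) != k + 1L)
    stop("need one rt center per species")
  structure(list(
    peptide = peptide, fractions = fractions,
    charge_weights = charge_weights, adduct_fraction = adduct_fraction,
    rt_centers = rt_centers, rt_width = rt_width, noise_cv = noise_cv,
    total_signal = total_signal, mz_tolerance_ppm = mz_tolerance_ppm,
    n_iso = as.integer(n_iso), seed = as.integer(seed)
  ), class = "ground_truth")
}

# lognormal multiplicative noise factors with unit mean and the given CV
.noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a centroided LC-MS1 run
#'
#' Places, for each species (oxidation count, charge state, adduct state,
#' isotope peak), centroid peaks at the theoretical m/z with Gaussian elution
#' profiles. The integrated area of each species is proportional to its
#' stoichiometric fraction times its charge weight; multiplicative noise with
#' the configured CV perturbs every centroid independently. Fully reproducible
#' from the ground-truth seed.
#'
#' @param truth A [ground_truth].
#' @param scan_interval Scan spacing in minutes (> 0).
#' @param rt_range Optional c(min, max) retention-time span; default covers
#'   all species' centers +/- 6 sigma.
#' @return A [scan_set]. The attribute `"species"` holds the per-species
#'   theoretical m/z table used at generation.
#' @export
simulate_lcms_run <- function(truth, scan_interval = 0.005, rt_range = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (scan_interval <= 0) stop("scan_interval must be > 0")
  if (is.null(rt_range))
    rt_range <- range(truth$rt_centers) + c(-6, 6) * truth$rt_width
  rts <- seq(rt_range[1], rt_range[2], by = scan_interval)

  k <- length(truth$fractions) - 1L
  charges <- as.integer(names(truth$charge_weights))
  adduct_states <- if (truth$adduct_fraction > 0) c(0, AMMONIUM_ADDUCT_SHIFT) else 0

  # one row per emitted centroid component
  comp_rows <- list()
  base_pf <- carbamidomethylate(truth$peptide)
  base_mass <- monoisotopic_mass(base_pf)
  for (n in 0:k) {
    mass_n <- base_mass + n * MODIFICATIONS$oxidation$mass_shift
    env <- isotope_distribution(
      composition_add(peptide_composition(base_pf), c(O = n)),
      n_peaks = truth$n_iso)
    for (zi in seq_along(charges)) {
      z <- charges[zi]
      for (ad in adduct_states) {
        ad_w <- if (ad == 0) 1 - truth$adduct_fraction else truth$adduct_fraction
        if (ad_w == 0) next
        area <- truth$total_signal * truth$fractions[n + 1L] *
          truth$charge_weights[[zi]] * ad_w
        if (area == 0) next
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          n_ox = n, charge = z, adduct = ad != 0,
          mz = mz(mass_n, z, ad) + env$offset * ISOTOPE_SPACING / z,
          iso = env$offset,
          area = area * env$abundance,
          rt_center = truth$rt_centers[n + 1L]
        )
      }
    }
  }
  comps <- do.call(rbind, comp_rows)

  # height matrix: components x scans; trapezoid over rt recovers the area
  heights <- outer(seq_len(nrow(comps)), seq_along(rts),
                   function(i, j) comps$area[i] *
                     stats::dnorm(rts[j], comps$rt_center[i], truth$rt_width))
  set.seed(truth$seed)
  if (truth$noise_cv > 0)
    heights <- heights * matrix(.noise_factors(length(heights), truth$noise_cv),
                                nrow = nrow(heights))

  floor_h <- max(heights) * 1e-12
  scans <- lapply(seq_along(rts), function(j) {
    keep <- heights[, j] > floor_h
    pk <- data.frame(mz = comps$mz[keep], intensity = heights[keep, j])
    pk <- pk[order(pk$mz), , drop = FALSE]
    list(rt = rts[j], peaks = pk)
  })
  out <- scan_set(scans, mz_tolerance_ppm = truth$mz_tolerance_ppm)
  attr(out, "species") <- comps
  attr(out, "truth") <- truth
  if (truth$adduct_fraction > 0 && 2L %in% charges && k >= 1) {
    # generation-time self-check of the adduct interference geometry: at
    # charge 2 the adduct monoisotopic peak of the n-ox species must fall
    # inside the instrument window around the +1 isotopic peak of the
    # (n+1)-ox species
    sep <- abs(AMMONIUM_ADDUCT_SHIFT - MODIFICATIONS$oxidation$mass_shift -
                 ISOTOPE_SPACING) / 2
    win <- mz(base_mass, 2L) * truth$mz_tolerance_ppm * 1e-6
    attr(out, "adduct_interferes") <- sep <= win
  }
  out
}

#' Label of a peptidoform for spectrum titles
#'
#' @param pf Peptidoform.
#' @return A string like `"VTVP.../oxidation@18,carbamidomethyl@13"`.
#' @export
peptidoform_label <- function(pf) {
  pf <- as_peptidoform(pf)
  if (!nrow(pf$mods)) return(pf$sequence)
  paste0(pf$sequence, "/",
         paste(sprintf("%s@%d", pf$mods$modification, pf$mods$position),
               collapse = ","))
}

#' Parse a peptidoform label back into a peptidoform
#' @param label String produced by [peptidoform_label].
#' @return A peptidoform.
#' @export
parse_peptidoform_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(peptidoform(parts))
  entries <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "@", fixed = TRUE)
  peptidoform(parts[1], mods = data.frame(
    position = vapply(fields, function(f) as.integer(f[2]), integer(1)),
    modification = vapply(fields, function(f) f[1], character(1))
  ))
}

#' Simulate an MS/MS spectrum of a peptidoform
#'
#' Emits the complete singly charged b- and y-ion series (oxidation mass
#' carried by every fragment covering a modified position) with equal base
#' intensity and multiplicative noise. The spectrum title carries the
#' ground-truth peptidoform label so localization tests can round-trip.
#'
#' @param pf Peptidoform (or sequence string).
#' @param charge Precursor charge recorded in the spectrum header.
#' @param noise_cv Multiplicative intensity noise CV.
#' @param seed Integer seed.
#' @param base_intensity Fragment base intensity.
#' @return A spectrum list (`title`, `pepmass`, `charge`, `peaks`) writable
#'   with [write_mgf].
#' @export
simulate_msms <- function(pf, charge = 2L, noise_cv = 0, seed = 1L,
                          base_intensity = 1000) {
  pf <- as_peptidoform(pf)
  frags <- theoretical_fragments(pf)
  set.seed(seed)
  intensity <- base_intensity * .noise_factors(nrow(frags), noise_cv)
  list(
    title = peptidoform_label(pf),
    pepmass = mz(monoisotopic_mass(pf), charge),
    charge = as.integer(charge),
    peaks = data.frame(mz = frags$mz, intensity = intensity)
  )
}

#' Simulate an internal-standard endpoint kinetics assay
#'
#' Generates per-substrate-concentration endpoint measurements from a
#' Michaelis-Menten model in the initial-rate regime: product formed in each
#' stopped reaction is `vmax * S / (Km + S) * reaction_time`. Substrate,
#' product and internal standard are emitted as areas through per-analyte
#' response factors, with substrate and product sharing one response factor
#' (the assumption under which internal-standard quantification operates).
#'
#' @param km Michaelis constant, uM (> 0).
#' @param vmax Maximal velocity, uM/min (> 0).
#' @param substrate_concs Substrate concentrations, uM (all > 0); default 8
#'   log-spaced points over the assayed 22-5610 uM range.
#' @param reaction_time Stopped-reaction time in minutes (> 0).
#' @param is_conc Internal-standard concentration, uM.
#' @param response_factor_analyte Area per uM for substrate and product.
#' @param response_factor_is Area per uM for the internal standard.
#' @param noise_cv Multiplicative noise CV applied to every area.
#' @param seed Integer seed.
#' @return A `kinetic_assay` data.frame with columns `S0`, `area_substrate`,
#'   `area_product`, `area_is`, `reaction_time`, `is_conc`, plus attribute
#'   `"truth"` holding the generating parameters and noiseless product
#'   concentrations.
#' @export
simulate_kinetics <- function(km, vmax,
                              substrate_concs = exp(seq(log(22), log(5610),
                                                        length.out = 8)),
                              reaction_time = 30,
                              is_conc = 100,
                              response_factor_analyte = 1,
                              response_factor_is = 1.2,
                              noise_cv = 0,
                              seed = 1L) {
  if (km <= 0 || vmax <= 0) stop("km and vmax must be > 0")
  if (any(substrate_concs <= 0)) stop("substrate concentrations must be > 0")
  if (reaction_time <= 0) stop("reaction_time must be > 0")
  S <- substrate_concs
  P <- vmax * S / (km + S) * reaction_time
  if (any(P >= S))
    stop("simulated conversion exceeds substrate; outside the initial-rate regime")
  set.seed(seed)
  noise <- matrix(.noise_factors(3 * length(S), noise_cv), ncol = 3)
  out <- data.frame(
    S0 = S,
    area_substrate = (S - P) * response_factor_analyte * noise[, 1],
    area_product = P * response_factor_analyte * noise[, 2],
    area_is = is_conc * response_factor_is * noise[, 3],
    reaction_time = reaction_time,
    is_conc = is_conc
  )
  attr(out, "truth") <- list(km = km, vmax = vmax, product_conc = P)
  class(out) <- c("kinetic_assay", "data.frame")
  out
}
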
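# Internal-standard quantification of product formation and Michaelis-Menten
# parameter estimation from endpoint assays.

#' Product concentration from an internal-standard assay row
#'
#' Under the shared-response-factor assumption — the relation between the
#' internal standard and the substrate equals the relation between the
#' standard and the product — the product concentration reduces to
#' `S0 * area_product / (area_substrate + area_product)`. The function also
#' evaluates the equivalent internal-standard-normalized form (product area
#' over IS area, scaled by the response factor calibrated from the total
#' analyte signal) and asserts that the two agree to 1e-9, as an internal
#' consistency check of the assumption.
#'
#' @param row One row of a kinetic assay (data.frame or list with `S0`,
#'   `area_substrate`, `area_product`, `area_is`, `is_conc`).
#' @return Product concentration in uM.
#' @export
product_concentration <- function(row) {
  total <- row$area_substrate + row$area_product
  if (total <= 0) stop("zero total analyte area")
  if (row$area_is <= 0) stop("internal-standard area must be > 0")
  p_direct <- row$S0 * row$area_product / total
  # response factor of the analyte relative to the IS, calibrated from the
  # total analyte signal; then [P] = is_conc * (area_product/area_is) / r_rel
  r_rel <- (total / row$S0) / (row$area_is / row$is_conc)
  p_is <- row$is_conc * (row$area_product / row$area_is) / r_rel
  stopifnot(abs(p_direct - p_is) <= 1e-9 * max(1, abs(p_direct)))
  p_direct
}

#' Initial velocity from an endpoint measurement
#'
#' `v = [P] / t` under the initial-rate assumption of a single stopped
#' reaction per substrate concentration.
#'
#' @param p_conc Product concentration, uM (>= 0).
#' @param reaction_time Reaction time, min (> 0).
#' @return Velocity in uM/min.
#' @export
initial_velocity <- function(p_conc, reaction_time) {
  if (any(reaction_time <= 0)) stop("reaction_time must be > 0")
  if (any(p_conc < 0)) stop("product concentration must be non-negative")
  p_conc / reaction_time
}

#' Velocities from a kinetic assay table
#'
#' @param assay A `kinetic_assay` data.frame (see [simulate_kinetics] or
#'   [read_kinetic_assay_csv]).
#' @return data.frame with columns `S` (uM) and `v` (uM/min).
#' @export
assay_velocities <- function(assay) {
  p <- vapply(seq_len(nrow(assay)), function(i)
    product_concentration(assay[i, , drop = FALSE]), numeric(1))
  data.frame(S = assay$S0, v = initial_velocity(p, assay$reaction_time))
}

#' Read a kinetic assay table from CSV
#'
#' Columns: `S0`, `area_substrate`, `area_product`, `area_is`,
#' `reaction_time`, `is_conc`.
#'
#' @param path CSV file.
#' @return A `kinetic_assay` data.frame.
#' @export
read_kinetic_assay_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("S0", "area_substrate", "area_product", "area_is",
            "reaction_time", "is_conc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("kinetic assay CSV missing columns: ", paste(miss, collapse = ", "))
  if (any(df$S0 <= 0)) stop("S0 must be > 0")
  class(df) <- c("kinetic_assay", "data.frame")
  df
}

#' Fit Michaelis-Menten parameters
#'
#' Nonlinear least squares on `v = vmax * S / (Km + S)`, initialized from a
#' Hanes-Woolf linearization (`S/v` regressed on `S`), with standard errors
#' from the Jacobian at convergence.
#'
#' @param points data.frame with columns `S` (uM) and `v` (uM/min); at least
#'   3 distinct substrate concentrations.
#' @return A `kinetic_parameters` list: `km`, `vmax`, `se_km`, `se_vmax`,
#'   `fit` (the nls object).
#' @export
fit_michaelis_menten <- function(points) {
  S <- points$S; v <- points$v
  if (length(unique(S)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  # Hanes-Woolf: S/v = S/vmax + Km/vmax
  ok <- v > 0
  if (sum(ok) < 3) stop("need at least 3 positive velocities")
  hw <- stats::lm(I(S[ok] / v[ok]) ~ S[ok])
  vmax0 <- 1 / stats::coef(hw)[[2]]
  km0 <- stats::coef(hw)[[1]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (km + S),
                      data = data.frame(S = S, v = v),
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 0, km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  if (est[["km"]] <= 0 || est[["vmax"]] <= 0)
    stop("Michaelis-Menten fit converged to non-positive parameters")
  structure(list(
    km = est[["km"]], vmax = est[["vmax"]],
    se_km = unname(se["km"]), se_vmax = unname(se["vmax"]),
    fit = fit
  ), class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("<kinetic_parameters> Km = %.4g uM (SE %.3g), vmax = %.4g uM/min (SE %.3g)\n",
              x$km, x$se_km, x$vmax, x$se_vmax))
  invisible(x)
}

#' Fit Michaelis-Menten parameters from an assay table
#'
#' Convenience wrapper: internal-standard product quantification, endpoint
#' velocities, then [fit_michaelis_menten].
#'
#' @param assay A `kinetic_assay` data.frame.
#' @return A `kinetic_parameters` object.
#' @export
fit_assay <- function(assay) {
  fit_michaelis_menten(assay_velocities(assay))
}
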
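#' Electron density from the refractive-index decrement
#'
#' The real part of the X-ray refractive index, n = 1 - delta + i*beta, is
#' proportional to electron density away from absorption edges:
#' n_e = 2*pi*delta / (lambda^2 * r0). With lambda and r0 in Angstrom the
#' result is electrons per cubic Angstrom.
#'
#' Negative delta values are permitted (noise or void voxels) and map to
#' negative electron densities.
#'
#' @param delta numeric vector/array of refractive-index decrements.
#' @param beam a [beam_geometry()].
#' @return electron density in e/Angstrom^3, same shape as `delta`.
#' @seealso [delta_from_electron_density()] for the inverse.
#' @export
#' @examples
#' electron_density_from_delta(1.435e-5, beam_geometry(6.2)) # ~0.800 e/A^3
electron_density_from_delta <- function(delta, beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  k <- physical_constants()
  2 * pi * delta / (beam$wavelength_angstrom^2 * k$r0_angstrom)
}

#' @rdname electron_density_from_delta
#' @param n_e electron density in e/Angstrom^3.
#' @export
delta_from_electron_density <- function(n_e, beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  k <- physical_constants()
  n_e * beam$wavelength_angstrom^2 * k$r0_angstrom / (2 * pi)
}

#' Mass density from electron density
#'
#' rho = n_e * A / (N_A * Z): electron density times molar mass per electron,
#' divided by Avogadro's number. Electron density in e/Angstrom^3 is converted
#' to e/cm^3 internally (1 cm^3 = 1e24 Angstrom^3).
#'
#' @param n_e electron density in e/Angstrom^3 (vector or array).
#' @param composition a `composition` object or formula string for the
#'   material whose A/Z ratio applies.
#' @return mass density in g/cm^3.
#' @seealso [electron_density_from_mass_density()] for the inverse (used by
#'   the phantom generator).
#' @export
#' @examples
#' mass_density_from_electron_density(0.7998, "SiO2") # ~2.66 g/cm^3 (quartz)
mass_density_from_electron_density <- function(n_e, composition) {
  comp <- .as_composition(composition)
  k <- physical_constants()
  n_e * 1e24 * (comp$A / comp$Z) / k$NA_mol
}

#' @rdname mass_density_from_electron_density
#' @param rho mass density in g/cm^3.
#' @export
electron_density_from_mass_density <- function(rho, composition) {
  comp <- .as_composition(composition)
  k <- physical_constants()
  rho * k$NA_mol / (comp$A / comp$Z) / 1e24
}

#' Refractive-index decrement of a material at given density
#'
#' Convenience chain rho -> n_e -> delta used when painting phantom volumes.
#'
#' @param rho mass density, g/cm^3.
#' @param composition material composition (object or formula string).
#' @param beam a [beam_geometry()].
#' @return delta (dimensionless).
#' @export
delta_from_mass_density <- function(rho, composition, beam) {
  delta_from_electron_density(
    electron_density_from_mass_density(rho, composition), beam)
}

#' A phase density estimate with uncertainty
#'
#' Pairs an electron density (e/Angstrom^3, 1-sigma width) with its mass
#' density under a hypothesized composition. The sigma maps linearly:
#' sigma_rho = sigma_ne * (A/Z) / N_A, exact for this affine conversion.
#'
#' @param electron_density center of the phase electron-density distribution,
#'   e/Angstrom^3.
#' @param sigma 1-sigma width in the same units (>= 0).
#' @param composition hypothesized material composition.
#' @return An object of class `density_estimate` with fields
#'   `electron_density`, `electron_density_sigma`, `mass_density`,
#'   `mass_density_sigma`, `composition`.
#' @export
#' @examples
#' density_estimate(0.7998, 0.01, "SiO2")
density_estimate <- function(electron_density, sigma = 0, composition) {
  stopifnot(is.finite(electron_density), is.finite(sigma), sigma >= 0)
  comp <- .as_composition(composition)
  structure(list(
    electron_density       = electron_density,
    electron_density_sigma = sigma,
    mass_density       = mass_density_from_electron_density(electron_density, comp),
    mass_density_sigma = mass_density_from_electron_density(sigma, comp),
    composition        = comp
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate [%s]: n_e = %.4f +/- %.4f e/A^3, rho = %.3f +/- %.3f g/cm^3\n",
              x$composition$text, x$electron_density, x$electron_density_sigma,
              x$mass_density, x$mass_density_sigma))
  invisible(x)
}

#' Bundled mineral candidate table
#'
#' Reference mass densities for the minerals relevant to silicified
#' microfossil taphonomy, shipped as a versioned CSV under `extdata`.
#' The mature-kerogen row carries a reference band (1.25-1.40 g/cm^3)
#' rather than a single value; its `reference_density_g_cm3` is the band
#' midpoint and the band limits are kept in dedicated columns.
#'
#' @param path optional path to an alternative CSV with columns
#'   `name,formula,reference_density_g_cm3[,band_low,band_high]`.
#' @return data.frame of candidates.
#' @export
mineral_candidates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mineral_candidates.csv", package = "pxct",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "reference_density_g_cm3")
  if (!all(need %in% names(df)))
    stop("candidate table must have columns: ", paste(need, collapse = ", "))
  if (any(df$reference_density_g_cm3 <= 0))
    stop("reference densities must be positive")
  df
}

#' Rank mineral candidates against a measured density
#'
#' Candidates are sorted by absolute difference between the estimated and
#' reference mass density (ties broken by candidate name), and each is
#' annotated with whether the difference lies within `k` sigma of the
#' estimate — the quantitative form of "the density matches mineral X".
#'
#' @param estimate a [density_estimate()].
#' @param candidates data.frame as returned by [mineral_candidates()], or any
#'   data.frame with `name` and `reference_density_g_cm3` columns.
#' @param k_sigma consistency threshold in units of the estimate's sigma
#'   (default 1).
#' @return the candidate data.frame sorted by match quality, with added
#'   columns `delta_g_cm3` (estimate minus reference), `abs_delta`,
#'   `within_k_sigma`.
#' @export
#' @examples
#' est <- density_estimate(
#'   electron_density_from_mass_density(4.82, "Fe2O3"),
#'   electron_density_from_mass_density(0.08, "Fe2O3"), "Fe2O3")
#' match_candidates(est)[1, "name"]  # "maghemite"
match_candidates <- function(estimate, candidates = mineral_candidates(),
                             k_sigma = 1) {
  stopifnot(inherits(estimate, "density_estimate"))
  if (!is.data.frame(candidates) || nrow(candidates) == 0)
    stop("candidate list is empty")
  d <- estimate$mass_density - candidates$reference_density_g_cm3
  out <- candidates
  out$delta_g_cm3 <- d
  out$abs_delta <- abs(d)
  out$within_k_sigma <- abs(d) <= k_sigma * estimate$mass_density_sigma
  out <- out[order(out$abs_delta, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a carbonaceous phase by mass density
#'
#' Thermally mature kerogen spans 1.19-1.77 g/cm^3 (inclusive), while
#' graphitic or amorphous carbon exceeds 2 g/cm^3; densities outside both
#' windows are indeterminate. This is the density leg of the biogenicity
#' argument: a carbonaceous phase in the mature-kerogen band is consistent
#' with matured biological organic matter, not with abiotic graphite.
#'
#' @param estimate a [density_estimate()] or a numeric mass density, g/cm^3.
#' @return character scalar: `"mature_kerogen"`, `"graphitic_or_amorphous"`,
#'   or `"indeterminate"`.
#' @export
#' @examples
#' classify_carbonaceous(1.39) # "mature_kerogen"
#' classify_carbonaceous(2.3)  # "graphitic_or_amorphous"
classify_carbonaceous <- function(estimate) {
  rho <- if (inherits(estimate, "density_estimate"))
    estimate$mass_density else estimate
  stopifnot(is.numeric(rho), length(rho) == 1, is.finite(rho))
  if (rho >= 1.19 && rho <= 1.77) "mature_kerogen"
  else if (rho > 2.0) "graphitic_or_amorphous"
  else "indeterminate"
}
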
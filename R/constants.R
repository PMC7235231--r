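#' Physical constants used throughout the package
#'
#' CODATA values for the classical electron radius and Avogadro's number,
#' and the photon energy-wavelength conversion product. All quantities are
#' fixed at construction; treat the returned list as read-only.
#'
#' @return A list with elements
#'   \describe{
#'     \item{r0_m}{classical electron radius, m}
#'     \item{r0_angstrom}{classical electron radius, Angstrom}
#'     \item{NA_mol}{Avogadro's number, 1/mol}
#'     \item{hc_keV_angstrom}{photon energy times wavelength, keV*Angstrom}
#'   }
#' @export
#' @examples
#' physical_constants()$r0_angstrom
physical_constants <- function() {
  list(
    r0_m           = 2.8179403262e-15,
    r0_angstrom    = 2.8179403262e-5,
    NA_mol         = 6.02214076e23,
    hc_keV_angstrom = 12.398420
  )
}

# IUPAC 2021 standard atomic weights (conventional values for intervals),
# elements 1-92. Names are element symbols; values in g/mol.
.atomic_weights <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.0983,
  Ca = 40.078, Sc = 44.955907, Ti = 47.867, V = 50.9415, Cr = 51.9961,
  Mn = 54.938043, Fe = 55.845, Co = 58.933194, Ni = 58.6934,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.63, As = 74.921595,
  Se = 78.971, Br = 79.904, Kr = 83.798, Rb = 85.4678, Sr = 87.62,
  Y = 88.905838, Zr = 91.224, Nb = 92.90637, Mo = 95.95, Tc = 97,
  Ru = 101.07, Rh = 102.90549, Pd = 106.42, Ag = 107.8682,
  Cd = 112.414, In = 114.818, Sn = 118.71, Sb = 121.76, Te = 127.6,
  I = 126.90447, Xe = 131.293, Cs = 132.90545196, Ba = 137.327,
  La = 138.90547, Ce = 140.116, Pr = 140.90766, Nd = 144.242,
  Pm = 145, Sm = 150.36, Eu = 151.964, Gd = 157.25, Tb = 158.925354,
  Dy = 162.5, Ho = 164.930329, Er = 167.259, Tm = 168.934219,
  Yb = 173.045, Lu = 174.9668, Hf = 178.486, Ta = 180.94788,
  W = 183.84, Re = 186.207, Os = 190.23, Ir = 192.217, Pt = 195.084,
  Au = 196.96657, Hg = 200.592, Tl = 204.38, Pb = 207.2,
  Bi = 208.9804, Po = 209, At = 210, Rn = 222, Fr = 223, Ra = 226,
  Ac = 227, Th = 232.0377, Pa = 231.03588, U = 238.02891
)

.atomic_numbers <- stats::setNames(seq_along(.atomic_weights),
                                   names(.atomic_weights))

#' Standard atomic weight table
#'
#' The bundled IUPAC 2021 standard atomic weights (conventional single values
#' where IUPAC gives an interval), elements H through U, together with atomic
#' numbers. This fixed table makes molar masses and A/Z ratios reproducible.
#'
#' @return A data.frame with columns `symbol`, `number`, `weight`.
#' @export
atomic_weight_table <- function() {
  data.frame(symbol = names(.atomic_weights),
             number = unname(.atomic_numbers),
             weight = unname(.atomic_weights),
             stringsAsFactors = FALSE)
}

#' Beam geometry for a PXCT acquisition
#'
#' Bundles photon energy, the derived X-ray wavelength and the reconstruction
#' voxel size. Defaults mirror a 6.2 keV acquisition with 28.53 nm voxels.
#'
#' @param photon_energy_keV photon energy in keV (> 0).
#' @param voxel_size_nm isotropic voxel width in nm (> 0).
#' @return An object of class `beam_geometry` with fields
#'   `photon_energy_keV`, `wavelength_angstrom`, `voxel_size_nm`.
#' @export
#' @examples
#' beam_geometry()$wavelength_angstrom  # ~2.0 Angstrom at 6.2 keV
beam_geometry <- function(photon_energy_keV = 6.2, voxel_size_nm = 28.53) {
  stopifnot(is.numeric(photon_energy_keV), length(photon_energy_keV) == 1,
            photon_energy_keV > 0,
            is.numeric(voxel_size_nm), length(voxel_size_nm) == 1,
            voxel_size_nm > 0)
  k <- physical_constants()
  structure(list(
    photon_energy_keV   = photon_energy_keV,
    wavelength_angstrom = k$hc_keV_angstrom / photon_energy_keV,
    voxel_size_nm       = voxel_size_nm
  ), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: %.4g keV (lambda = %.5g Angstrom), voxel %.4g nm\n",
              x$photon_energy_keV, x$wavelength_angstrom, x$voxel_size_nm))
  invisible(x)
}
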
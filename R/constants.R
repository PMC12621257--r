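#' Physical constants and element data
#'
#' Single source of truth for unit conversions and bond detection.
#'
#' @name uvvisbench-constants
#' @keywords internal
NULL

# hc in eV*nm (CODATA-consistent); all wavelength/energy conversions use this.
HC_EV_NM <- 1239.841984

# Gaussian FWHM/sigma ratio, 2*sqrt(2*ln 2)
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert wavelength (nm) to photon energy (eV)
#'
#' @param lambda_nm wavelength(s) in nm, all > 0
#' @param hc Planck constant times speed of light, eV*nm
#' @return energies in eV
#' @export
ev_from_nm <- function(lambda_nm, hc = HC_EV_NM) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop("wavelengths must be finite and positive", call. = FALSE)
  }
  hc / lambda_nm
}

#' Convert photon energy (eV) to wavelength (nm)
#'
#' @param e_ev energies in eV, all > 0
#' @inheritParams ev_from_nm
#' @return wavelengths in nm
#' @export
nm_from_ev <- function(e_ev, hc = HC_EV_NM) {
  if (any(!is.finite(e_ev)) || any(e_ev <= 0)) {
    stop("energies must be finite and positive", call. = FALSE)
  }
  hc / e_ev
}

#' Convert wavenumber (cm^-1) to energy (eV)
#'
#' A 100 cm^-1 resampling interval corresponds to ~0.0124 eV.
#'
#' @param wn wavenumbers in cm^-1
#' @inheritParams ev_from_nm
#' @return energies in eV
#' @export
cm1_to_ev <- function(wn, hc = HC_EV_NM) {
  # hc in eV*cm = hc[eV*nm] * 1e-7
  wn * hc * 1e-7
}

# Covalent radii (Angstrom), Cordero et al. 2008 single-bond set.
# Fe is the low-spin value; detection tolerance absorbs the spin-state spread.
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  As = 1.19, Se = 1.20, Br = 1.20, I = 1.39,
  Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32,
  Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Os = 1.44, Ir = 1.41,
  Pt = 1.36, Au = 1.36
)

TRANSITION_METALS <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

#' Look up covalent radii for element symbols
#'
#' @param elements character vector of element symbols
#' @return numeric vector of radii in Angstrom
#' @export
covalent_radius <- function(elements) {
  r <- COVALENT_RADII[elements]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}
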
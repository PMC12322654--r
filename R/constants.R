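#' Physical constants used throughout the package
#'
#' CODATA-2018 exact values. The Eyring prefactor is kB*T/h with the
#' transmission coefficient fixed at 1; energies are in kcal/mol.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{R_kcal}{molar gas constant, kcal/(mol K)}
#'   \item{c}{speed of light, m/s}
#'   \item{NA_mol}{Avogadro constant, 1/mol}
#'   \item{kappa}{Eyring transmission coefficient (fixed at 1)}
#'   \item{hc_eV_nm}{photon energy-wavelength product, eV nm}
#' }
#' @export
azo_constants <- list(
  kB       = 1.380649e-23,
  h        = 6.62607015e-34,
  R_kcal   = 1.987204e-3,
  c        = 2.99792458e8,
  NA_mol   = 6.02214076e23,
  kappa    = 1,
  hc_eV_nm = 1239.842
)
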
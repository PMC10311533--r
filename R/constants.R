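# Physical constants (CODATA 2018). Internal energy unit is cm^-1; the
# susceptibility machinery works in Gaussian-cgs where erg G^-2 = cm^3.
.const <- list(
  N_A        = 6.02214076e23,     # mol^-1
  mu_B_cgs   = 9.2740100783e-21,  # erg G^-1
  k_B_cgs    = 1.380649e-16,      # erg K^-1
  k_B_cm     = 0.695034800,       # cm^-1 K^-1
  hc_erg_cm  = 1.9864458571e-16,  # erg cm (converts cm^-1 -> erg)
  # e^2/(4 pi eps0) expressed as cm^-1 * Angstrom: Coulomb energy of two
  # elementary charges 1 A apart.
  e2_cm_ang  = 116140.0,
  # cgs molar (cm^3 mol^-1) -> SI per-molecule (m^3) conversion for chi
  chi_cgs_to_si = 4 * pi * 1e-6 / 6.02214076e23
)

# Unit flags for susceptibility tensors
.chi_units <- c("cgs_molar_cm3_per_mol", "si_molecular_m3")

#' Bleaney constants for the lanthanide(III) ions
#'
#' Dimensionless Bleaney constants \eqn{C_J}, on the customary scale
#' normalised to \eqn{C_{Dy} = -100}. They set the relative magnitude and
#' sign of the axial pseudocontact shift across an isostructural Ln(III)
#' series in Bleaney's theory.
#'
#' @return Named numeric vector keyed by element symbol.
#' @examples
#' bleaney_constants()[["Dy"]]
#' @export
bleaney_constants <- function() {
  c(Ce = -6.3, Pr = -11, Nd = -4.2, Sm = -0.7, Eu = 4,
    Tb = -86, Dy = -100, Ho = -39, Er = 33, Tm = 53, Yb = 22)
}
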
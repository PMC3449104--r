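#' Physical constants and solvent parameters
#'
#' Bundle of the physical constants used throughout the electrodiffusion
#' calculations (SI units, CODATA exact values), together with the absolute
#' temperature and the solvent relative permittivity.
#'
#' @param temperature Absolute temperature in kelvin. Default 298.15 K (25 C).
#' @param epsilon_r Relative permittivity of the solvent inside and outside
#'   the pore. Default 80 (bulk water).
#'
#' @return A list with components `kB` (J/K), `e` (C), `N_A` (1/mol),
#'   `F` (C/mol), `R` (J/mol/K), `eps0` (F/m), `epsilon_r`, `T` (K), and the
#'   thermal voltage `Vt_mV` = kB*T/e in millivolts (about 25.7 mV at 25 C).
#' @examples
#' k <- phys_constants()
#' k$Vt_mV  # ~25.7
#' @export
phys_constants <- function(temperature = 298.15, epsilon_r = 80) {
  stopifnot(temperature > 0, epsilon_r > 0)
  kB <- 1.380649e-23
  e <- 1.602176634e-19
  N_A <- 6.02214076e23
  list(
    kB = kB, e = e, N_A = N_A,
    F = e * N_A, R = kB * N_A,
    eps0 = 8.8541878128e-12,
    epsilon_r = epsilon_r,
    T = temperature,
    Vt_mV = 1000 * kB * temperature / e
  )
}
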
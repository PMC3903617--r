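#' Physical constants used throughout the package
#'
#' Single source of truth for the constants entering the energy model and
#' the kinetic/thermodynamic analyses.
#'
#' @format A list with components:
#' \describe{
#'   \item{R_kcal}{Gas constant, 1.9872e-3 kcal mol^-1 K^-1.}
#'   \item{kB}{Boltzmann constant, J K^-1.}
#'   \item{h}{Planck constant, J s.}
#'   \item{T_ref}{Reference temperature, 298.15 K (25 C).}
#'   \item{coulomb_k}{Coulomb prefactor, 332.0637 kcal A mol^-1 e^-2.}
#' }
#' @export
ab_constants <- list(
  R_kcal    = 1.9872e-3,
  kB        = 1.380649e-23,
  h         = 6.62607015e-34,
  T_ref     = 298.15,
  coulomb_k = 332.0637
)

# kB*T/h in s^-1 at temperature T (Eyring prefactor)
eyring_prefactor <- function(T) ab_constants$kB * T / ab_constants$h
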
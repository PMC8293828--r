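#' Physical constants in wavenumber units
#'
#' All energies in this package are expressed in wavenumbers (cm^-1) and all
#' times in femtoseconds, the conventional units for exciton dynamics in
#' pigment aggregates. `hbar` converts between the two (`cm^-1 * fs`) and
#' `k_B` converts temperatures in Kelvin to thermal energies in cm^-1.
#'
#' @return Named list with elements `hbar` (5308.837 cm^-1 fs) and
#'   `k_B` (0.695035 cm^-1 / K).
#' @examples
#' hops_constants()$hbar
#' @export
hops_constants <- function() {
  list(hbar = 5308.837, k_B = 0.695035)
}

# internal shorthands used throughout
.hbar <- 5308.837
.kB <- 0.695035
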
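#' Physical constants
#'
#' Named vector of the physical constants used by every dielectric and force
#' routine in the package, in SI units:
#' \describe{
#'   \item{eps0}{vacuum permittivity, 8.854e-12 F/m}
#'   \item{k_B}{Boltzmann constant, 1.38e-23 J/K}
#'   \item{e}{elementary charge, 1.602e-19 C}
#' }
#' Kept in a single table so all modules share identical values.
#'
#' @format Named numeric vector of length 3.
#' @export
phys_const <- c(
  eps0 = 8.854e-12,
  k_B  = 1.38e-23,
  e    = 1.602e-19
)
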
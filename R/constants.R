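#' Physical constants and unit conventions
#'
#' All coordinates are in Angstrom (A), times in picoseconds (ps), energies in
#' kcal/mol and temperatures in Kelvin. Observables never convert units
#' internally; the contact-switching sharpness beta is in 1/A, so coordinates
#' must already be in A when they reach the contact module.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K): 0.0019872041.}
#'   \item{T_ref}{Reference temperature for fluctuation scaling, K (25 C).}
#'   \item{ca_spacing}{Consecutive C-alpha virtual bond length, A.}
#'   \item{residue_volume}{Mean amino-acid residue volume, A^3, used by the
#'     equal-volume sphere-radius convention when residue identity is unknown.}
#' }
#' @export
cq_constants <- list(
  kB             = 0.0019872041,
  T_ref          = 298.15,
  ca_spacing     = 3.8,
  residue_volume = 134
)
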
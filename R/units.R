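#' Reduced-unit to physical-unit mapping
#'
#' The engine works in reduced Lennard-Jones units (sigma = epsilon = m =
#' k_B = 1). For reporting, a mapping to physical units is anchored on the
#' rigid solute: its contour length in reduced units is mapped to 2.4 nm,
#' the persistent end-to-end length of a rod-like carotenoid, and the
#' reduced temperature T = 1 is mapped to 300 K (so epsilon = k_B * 300 K
#' = 0.596 kcal/mol).
#'
#' @param contour_sigma Rigid-solute contour length in reduced length units
#'   that should map to `contour_nm`.
#' @param contour_nm Physical contour length of the rigid rod, nm.
#' @param temperature_K Physical temperature mapped to reduced T = 1.
#' @return A `ldflex_units` list with conversion factors: `nm_per_sigma`,
#'   `kcal_per_epsilon`, `K_per_T`.
#' @export
#' @examples
#' u <- unit_map(contour_sigma = 6.79)
#' u$nm_per_sigma
unit_map <- function(contour_sigma = 6.79, contour_nm = 2.4,
                     temperature_K = 300) {
  stopifnot_scalar_number(contour_sigma, "contour_sigma", positive = TRUE)
  structure(
    list(
      nm_per_sigma = contour_nm / contour_sigma,
      kcal_per_epsilon = 0.0019872041 * temperature_K, # k_B in kcal/mol/K
      K_per_T = temperature_K
    ),
    class = "ldflex_units"
  )
}

#' Convert reduced lengths/energies to physical units
#'
#' @param x Numeric vector in reduced units.
#' @param units A [unit_map()] object.
#' @param what One of `"length"` (to nm) or `"energy"` (to kcal/mol).
#' @return Numeric vector in physical units.
#' @export
to_physical <- function(x, units = unit_map(), what = c("length", "energy")) {
  what <- match.arg(what)
  switch(what,
    length = x * units$nm_per_sigma,
    energy = x * units$kcal_per_epsilon
  )
}
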
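# Physical constants and energy-unit conversions.
# Internal energy unit is pN nm throughout (1 pN nm = 1e-21 J = 1 zJ).

.kB_pn_nm <- 0.01380649 # Boltzmann constant, pN nm / K (exact SI)
.pn_nm_per_kcal_mol <- 4184 / 6.02214076e23 * 1e21 # = 6.947695 pN nm

#' Convert between energy units
#'
#' Converts energies between the units used in hairpin force calculations:
#' `"pN_nm"` (piconewton nanometre, the package's internal unit),
#' `"kcal_mol"` (kilocalorie per mole, the unit of nearest-neighbor
#' thermodynamic tables), and `"kT"` (thermal energy at a given temperature).
#'
#' @param x Numeric vector of energies.
#' @param from,to Units, one of `"pN_nm"`, `"kcal_mol"`, `"kT"`.
#' @param temperature Temperature in kelvin; only used when converting
#'   from or to `"kT"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_energy(1, "kcal_mol", "pN_nm") # 6.9477
#' @export
convert_energy <- function(x, from = "pN_nm", to = "kcal_mol",
                           temperature = 310.15) {
  units <- c("pN_nm", "kcal_mol", "kT")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  to_pn <- switch(from,
    pN_nm = 1,
    kcal_mol = .pn_nm_per_kcal_mol,
    kT = .kB_pn_nm * temperature
  )
  from_pn <- switch(to,
    pN_nm = 1,
    kcal_mol = .pn_nm_per_kcal_mol,
    kT = .kB_pn_nm * temperature
  )
  x * to_pn / from_pn
}

# thermal energy in pN nm
kBT <- function(temperature) .kB_pn_nm * temperature
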
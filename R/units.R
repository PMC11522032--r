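# Unit system: lengths in Angstrom, time in fs, energy in kcal/mol, mass in
# amu. Stress is carried natively in kcal mol^-1 A^-3; conversion to MPa is
# applied only at the reporting layer.

#' Unit conversion constants
#'
#' `kcalmolA3_to_MPa`: multiply a stress in kcal mol^-1 A^-3 to get MPa.
#' `A_fs_to_m_s`: multiply a speed in Angstrom/fs to get m/s.
#' `kB`: Boltzmann constant in kcal mol^-1 K^-1.
#' `mv2e`: multiply `mass[amu] * v[A/fs]^2` to get kcal mol^-1 (its inverse
#' converts force/mass to acceleration in A fs^-2).
#' @export
fibril_units <- function() {
  list(kcalmolA3_to_MPa = 6947.7,
       A_fs_to_m_s = 1e5,
       kB = 0.0019872041,
       mv2e = 2390.0574)
}

#' Convert a native stress to MPa
#' @param sigma stress in kcal mol^-1 A^-3.
#' @export
stress_to_MPa <- function(sigma) sigma * fibril_units()$kcalmolA3_to_MPa

#' Convert a pulling speed from Angstrom/fs to m/s
#' @param v speed in Angstrom/fs.
#' @export
speed_to_m_s <- function(v) v * fibril_units()$A_fs_to_m_s
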
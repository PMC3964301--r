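## Internal unit system: length Angstrom, time ps, mass Da, energy kcal/mol.
## Velocities are Angstrom/ps; forces are kcal/(mol Angstrom) internally and
## converted to pN only at the reporting boundary.

#' Physical constants of the internal unit system
#'
#' The engine works in Angstrom / picosecond / Dalton / kcal per mol.
#' `kB` is Boltzmann's constant in kcal mol^-1 K^-1; `kcalmolA_per_pN` and
#' `pN_per_kcalmolA` convert between the internal force unit and piconewtons
#' (1 kcal mol^-1 A^-1 = 69.4770 pN); `Da_to_kcalps` converts a mass in Da to
#' the unit in which kinetic energy (1/2) m v^2 comes out in kcal/mol for v in
#' A/ps.
#'
#' @format Named list of scalars.
#' @export
go_constants <- list(
  kB             = 0.0019872,           # kcal mol^-1 K^-1
  pN_per_kcalmolA = 69.4770,            # 4184 J / N_A / 1e-10 m, in pN
  Da_to_kcalps   = 10 / 4184            # Da (A/ps)^2 -> kcal/mol
)

#' Convert a spring constant from kcal mol^-1 A^-2 to pN/A
#'
#' Spring constants in the simulation literature are quoted either in
#' kcal mol^-1 A^-2 (simulation-internal) or pN/A (AFM convention); the common
#' all-atom pulling value of 4 kcal mol^-1 A^-2 corresponds to about 278 pN/A.
#'
#' @param k Spring constant in kcal mol^-1 A^-2 (non-negative).
#' @return Spring constant in pN/A.
#' @seealso [convert_spring_constant_inverse()]
#' @examples
#' convert_spring_constant(4)    # ~278 pN/A
#' @export
convert_spring_constant <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0))
  k * go_constants$pN_per_kcalmolA
}

#' Convert a spring constant from pN/A to kcal mol^-1 A^-2
#'
#' Algebraic inverse of [convert_spring_constant()].
#'
#' @param K Spring constant in pN/A.
#' @return Spring constant in kcal mol^-1 A^-2.
#' @export
convert_spring_constant_inverse <- function(K) {
  stopifnot(is.numeric(K), all(K >= 0))
  K / go_constants$pN_per_kcalmolA
}

#' Instantaneous pulling force of a constant-velocity spring
#'
#' The pulled bead is tethered by a harmonic spring to a dummy anchor that
#' moves at constant velocity; the reported force is `F = K * (D - D0)` where
#' `D` is the current anchor-to-bead distance and `D0` its value at the start
#' of pulling. The force is negative when the anchor lags behind the bead
#' (D < D0), e.g. right after a rupture when the stored extension snaps back.
#'
#' @param D Current dummy-atom to pulled-bead distance, Angstrom.
#' @param D0 Reference (initial frame) distance, Angstrom.
#' @param K Spring constant, pN/A (> 0).
#' @return Force in pN.
#' @export
spring_force <- function(D, D0, K) {
  stopifnot(is.numeric(D), is.numeric(D0), is.numeric(K), all(K > 0))
  K * (D - D0)
}
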
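# Unit conversions.  Internal units are kcal/mol, Angstrom and fs throughout;
# conversions are applied only at the reporting boundary.

#' Convert a coarse-grained pulling speed to meters per second
#'
#' Coarse-grained speeds are given in Angstrom per molecular time unit
#' (1 MTU = 4.89 fs).  Because events in the coarse-grained model occur about
#' 1000 times faster than in all-atom dynamics, the reported physical speed
#' divides the raw unit conversion by that scale factor.
#'
#' @param speed pulling speed in A/MTU.
#' @param scaleFactor coarse-grained time-scale factor (default 1000); use 1
#'   for the raw physical speed.
#' @param report if TRUE, round to 2 significant figures as speeds are
#'   conventionally quoted.
#' @return speed in m/s.
#' @examples
#' cgSpeedToMps(0.02, report = TRUE)   # ~0.4 m/s
#' cgSpeedToMps(0.0005, report = TRUE) # ~0.01 m/s
#' @export
cgSpeedToMps <- function(speed, scaleFactor = 1000, report = FALSE) {
  stopifnot(all(speed > 0))
  v <- (speed * 1e-10 / (.mtuFs * 1e-15)) / scaleFactor
  if (report) signif(v, 2) else v
}

#' Convert an all-atom pulling speed to meters per second
#'
#' @param speed pulling speed in A/ns.
#' @return speed in m/s (speed x 0.1).
#' @examples
#' aaSpeedToMps(10)  # 1 m/s
#' @export
aaSpeedToMps <- function(speed) {
  stopifnot(all(speed >= 0))
  speed * 0.1
}

#' Convert a force from kcal/mol/A to piconewtons
#'
#' @param f force in kcal/mol/A.
#' @return force in pN (f x 69.4786).
#' @examples
#' forceToPN(8.0)  # 555.8 pN, conventionally reported as 556 pN
#' @export
forceToPN <- function(f) f * .pNperKcalMolA

#' Unit-system constants
#'
#' @return named list of the conversion constants used at the reporting
#'   boundary: pN per kcal/mol/A, fs per MTU, Boltzmann constant in
#'   kcal/mol/K, and the coarse-grained time-scale factor.
#' @export
unitSystem <- function() {
  list(pN_per_kcal_mol_A = .pNperKcalMolA, fs_per_MTU = .mtuFs,
       kB_kcal_mol_K = .kB, cg_time_scale = 1000)
}
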
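# User-facing energy and force evaluators.

.dynParVector <- function(p)
  c(p@aCore, p@dBond, p@rBond, p@sBond, p@dContact, p@rContact, p@sContact)

#' Dynamic disulfide double-well potential
#'
#' Distance-dependent potential for a pair of cysteine side-centers: a deep
#' bonded well at \code{rBond} whose depth encodes the redox environment, a
#' shallow contact minimum at \code{rContact} that is unaffected by the redox
#' setting, a repulsive core and a smooth decay to zero.  Form:
#' \deqn{U(r) = A/r^{12} - D_b e^{-(r-r_b)^2/2\sigma_b^2}
#'            - D_c e^{-(r-r_c)^2/2\sigma_c^2}}
#'
#' @param r side-center distance(s), A.
#' @param params a \code{DynamicSSParams}.
#' @return data.frame with columns \code{r}, \code{energy} (kcal/mol) and
#'   \code{force} (radial force \eqn{-dU/dr}, kcal/mol/A).
#' @examples
#' uDynSS(4.0)$energy  # approximately -5.5 (weakly oxidizing default)
#' @export
uDynSS <- function(r, params = DynamicSSParams()) {
  stopifnot(all(r > 0))
  m <- evalDynSS(r, .dynParVector(params))
  data.frame(r = r, energy = m[, 1], force = m[, 2])
}

#' Triplet repulsion between candidate disulfide partners
#'
#' Penalty applied when one cysteine has two partners simultaneously within
#' bonding range; it enforces the valence of the disulfide bond.  Symmetric
#' in the two distances and negligible unless both are short.
#'
#' @param rki,rkj distances from cysteine k to candidate partners i and j, A.
#' @param params a \code{TripletParams}.
#' @return energy in kcal/mol (>= 0).
#' @export
uSSSTriplet <- function(rki, rkj, params = TripletParams()) {
  stopifnot(all(rki > 0), all(rkj > 0))
  n <- max(length(rki), length(rkj))
  evalTriplet(rep_len(rki, n), rep_len(rkj, n),
              c(params@a, params@b, params@c, params@d))
}

#' Flat-bottom breaking restraint
#'
#' Piecewise potential: harmonic \eqn{k(r-r_1)^2} below \code{r1}, zero on
#' [r1, r2], harmonic \eqn{k(r-r_2)^2} on [r2, r3], and linear above
#' \code{r3} where the restraint exerts the constant force
#' \eqn{2k(r_3-r_2)}.  With the default constants that force is
#' 8 kcal/mol/A = 555.8 pN (reported as 556 pN).
#'
#' @param r distance(s), A.
#' @param params a \code{RestraintParams}.
#' @return data.frame with columns \code{r}, \code{energy} (kcal/mol) and
#'   \code{force} (radial force \eqn{-dU/dr}, kcal/mol/A).
#' @examples
#' uFlatBottom(5.0)$force          # -8 kcal/mol/A
#' forceToPN(abs(uFlatBottom(5.0)$force))  # 555.8 pN
#' @export
uFlatBottom <- function(r, params = RestraintParams()) {
  stopifnot(all(r > 0))
  m <- evalFlatBottom(r, c(params@k, params@r1, params@r2, params@r3))
  data.frame(r = r, energy = m[, 1], force = m[, 2])
}

#' Background (Go-type) energy and forces
#'
#' Structure-based potential: harmonic backbone and side-center bonds, 12-10
#' native-contact wells, quartic excluded volume and cosine pseudo-dihedrals.
#' No disulfide terms are evaluated.
#'
#' @param coords bead coordinates (nBeads x 3), A.
#' @param topology a \code{ChainTopology}.
#' @param go \code{GoParams}.
#' @return list with \code{energy} (kcal/mol) and \code{forces}
#'   (nBeads x 3, kcal/mol/A).
#' @export
goEnergyForces <- function(coords, topology, go = GoParams()) {
  stopifnot(all(is.finite(coords)))
  sys <- .buildSystem(topology, go, RedoxModel("none"))
  r <- engineEnergy(sys, coords)
  list(energy = r$energy, forces = r$forces)
}

#' Total energy and forces under a redox model
#'
#' Sum of the structure-based background and the mode-dependent disulfide
#' terms; per-pair disulfide energies are exposed for bond bookkeeping.
#'
#' @param coords bead coordinates (nBeads x 3), A.
#' @param topology a \code{ChainTopology}.
#' @param go \code{GoParams}.
#' @param redox a \code{RedoxModel}.
#' @return list with \code{energy}, \code{go}, \code{ss}, \code{forces} and
#'   \code{ssPairEnergies} (named by the residue pairs, dynamic and
#'   restraint modes).
#' @export
totalEnergyForces <- function(coords, topology, go = GoParams(),
                              redox = RedoxModel("dynamic")) {
  stopifnot(all(is.finite(coords)))
  sys <- .buildSystem(topology, go, redox)
  r <- engineEnergy(sys, coords)
  ssE <- r$ssPairEnergies
  if (length(ssE) > 0) {
    prs <- if (redox@mode == "dynamic") {
      cys <- sort(topology@cysteines)
      t(combn(cys, 2)) + 1L
    } else topology@crosslinks + 1L
    names(ssE) <- sprintf("%d-%d", prs[, 1], prs[, 2])
  }
  list(energy = r$energy, go = r$go, ss = r$ss, forces = r$forces,
       ssPairEnergies = ssE)
}

#' Relax a conformation to a local minimum
#'
#' Deterministic adaptive steepest descent under the full potential for the
#' given redox model.
#'
#' @param topology a \code{ChainTopology}.
#' @param coords starting coordinates; defaults to the native conformation.
#' @param go \code{GoParams}.
#' @param redox a \code{RedoxModel}.
#' @param maxSteps iteration cap.
#' @param fTol gradient-component tolerance, kcal/mol/A.
#' @return list with \code{coords}, \code{energy}, \code{gradMax},
#'   \code{iterations}.
#' @export
relaxStructure <- function(topology, coords = nativeCoords(topology),
                           go = GoParams(), redox = RedoxModel("none"),
                           maxSteps = 2000L, fTol = 1e-4) {
  sys <- .buildSystem(topology, go, redox)
  engineMinimize(sys, coords, maxSteps = as.integer(maxSteps), fTol = fTol)
}
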
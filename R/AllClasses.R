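# S4 classes for topologies, parameter sets, protocols and trajectories.

#' Chain topology of a coarse-grained protein model
#'
#' Beads (one backbone center per residue, at most one side-center per
#' residue), backbone connectivity, native contacts grouped by structural
#' element, cysteine positions, native crosslinks and pulling anchors.
#' Residue ordinals are 0-based internally; all user-facing printing and
#' analysis output is 1-based.
#'
#' @slot nResidues number of residues.
#' @slot beads data.frame with columns \code{bead} (0-based bead index),
#'   \code{residue} (0-based residue ordinal), \code{kind} (\code{"bb"} or
#'   \code{"sc"}) and \code{resname} (3-letter code).
#' @slot backboneBonds data.frame \code{i}, \code{j}, \code{b0} (bead
#'   indices, equilibrium length in Angstrom).
#' @slot sideBonds data.frame \code{i}, \code{j}, \code{b0} tethering each
#'   side-center to its backbone bead.
#' @slot nativeContacts data.frame \code{i}, \code{j} (backbone bead
#'   indices), \code{r0} (native distance, A), \code{element} (label).
#' @slot cysteines integer vector of cysteine residue ordinals (0-based).
#' @slot crosslinks two-column integer matrix of native disulfide pairs
#'   (0-based residue ordinals).
#' @slot anchors length-2 integer vector of pulling anchor residues (0-based).
#' @slot nativeCoords numeric matrix (nBeads x 3) of native coordinates, A.
#' @slot cbeta numeric matrix (nResidues x 3) of C-beta positions (NA rows
#'   where unavailable); used by the bond-presence criterion when loaded from
#'   an all-atom structure.
#' @slot elements data.frame mapping residues to element labels.
#' @export
setClass("ChainTopology", representation(
  nResidues = "integer",
  beads = "data.frame",
  backboneBonds = "data.frame",
  sideBonds = "data.frame",
  nativeContacts = "data.frame",
  cysteines = "integer",
  crosslinks = "matrix",
  anchors = "integer",
  nativeCoords = "matrix",
  cbeta = "matrix",
  elements = "data.frame"
))

setValidity("ChainTopology", function(object) {
  msg <- character(0)
  n <- object@nResidues
  bb <- object@beads[object@beads$kind == "bb", ]
  if (nrow(bb) != n) msg <- c(msg, "each residue needs exactly one backbone bead")
  if (anyDuplicated(object@beads$bead)) msg <- c(msg, "duplicate bead indices")
  sc <- object@beads[object@beads$kind == "sc", ]
  if (anyDuplicated(sc$residue)) msg <- c(msg, "more than one side-center for a residue")
  if (!all(is.finite(object@nativeCoords))) msg <- c(msg, "non-finite native coordinates")
  if (n > 1 && nrow(object@backboneBonds) != n - 1)
    msg <- c(msg, "backbone beads must form a single unbranched chain")
  if (nrow(object@nativeContacts) > 0) {
    sep <- abs(object@nativeContacts$i - object@nativeContacts$j)
    if (any(sep < 3)) msg <- c(msg, "native contacts require |i-j| >= 3")
  }
  if (nrow(object@crosslinks) > 0 &&
      !all(object@crosslinks %in% object@cysteines))
    msg <- c(msg, "crosslink pairs must connect cysteines")
  if (length(object@anchors) == 2 && object@anchors[1] == object@anchors[2])
    msg <- c(msg, "anchors must be distinct")
  if (length(msg)) msg else TRUE
})

#' Synthetic toy-fold specification
#'
#' Ordered secondary-structure blocks (helix-like, sheet-like, loop) that tile
#' the chain, a crosslink architecture, and a seed.  Identical spec + seed
#' always produce bitwise-identical structures.
#'
#' @slot nResidues chain length.
#' @slot blocks data.frame with columns \code{type} (\code{"helix"},
#'   \code{"sheet"}, \code{"loop"}) and \code{length}.
#' @slot crosslinks two-column integer matrix of 0-based residue pairs to be
#'   crosslinked in the native structure.
#' @slot seed integer seed.
#' @export
setClass("ToyFoldSpec", representation(
  nResidues = "integer",
  blocks = "data.frame",
  crosslinks = "matrix",
  seed = "integer"
))

setValidity("ToyFoldSpec", function(object) {
  msg <- character(0)
  if (sum(object@blocks$length) != object@nResidues)
    msg <- c(msg, "blocks must tile [0, nResidues)")
  if (!all(object@blocks$type %in% c("helix", "sheet", "loop")))
    msg <- c(msg, "block types must be helix/sheet/loop")
  if (nrow(object@crosslinks) > 0) {
    if (any(object@crosslinks < 0 | object@crosslinks >= object@nResidues))
      msg <- c(msg, "crosslink residues out of range")
    if (any(object@crosslinks[, 1] == object@crosslinks[, 2]))
      msg <- c(msg, "crosslink pairs must be distinct residues")
  }
  if (length(msg)) msg else TRUE
})

#' Background (Go-type) potential parameters
#'
#' @slot bondK backbone bond spring constant, kcal/mol/A^2 (energy 0.5 k dr^2).
#' @slot bondB0 backbone bond equilibrium length, A.
#' @slot scBondK side-center tether spring constant.
#' @slot epsContact native-contact well depth (12-10 form), kcal/mol.
#' @slot sigmaEV excluded-volume diameter for backbone pairs, A.
#' @slot sigmaEVSide excluded-volume diameter involving side-centers, A.
#' @slot kEV quartic excluded-volume strength, kcal/mol/A^4.
#' @slot dihedralK pseudo-dihedral stiffness, kcal/mol.
#' @slot contactCutoff native-contact detection cutoff, A.
#' @export
setClass("GoParams", representation(
  bondK = "numeric", bondB0 = "numeric", scBondK = "numeric",
  epsContact = "numeric", sigmaEV = "numeric", sigmaEVSide = "numeric",
  kEV = "numeric", dihedralK = "numeric", contactCutoff = "numeric"
))

setValidity("GoParams", function(object) {
  vals <- c(object@bondK, object@epsContact, object@kEV, object@dihedralK)
  if (any(vals < 0)) return("all strengths must be >= 0")
  if (object@sigmaEV <= 0 || object@sigmaEVSide <= 0) return("sigma must be > 0")
  TRUE
})

#' Dynamic disulfide double-well parameters
#'
#' The bonded-well depth \code{dBond} encodes the redox potential of the
#' medium: 5.5 kcal/mol for a weakly oxidizing and 11.0 kcal/mol for a highly
#' oxidizing environment.  Changing \code{dBond} leaves the secondary
#' (contact) minimum untouched, so the barrier between formed and broken bond
#' scales with the redox setting.
#'
#' @slot dBond bonded-well depth, kcal/mol.
#' @slot rBond bonded-well position, A.
#' @slot sBond bonded-well width, A.
#' @slot dContact contact-minimum depth, kcal/mol.
#' @slot rContact contact-minimum position, A.
#' @slot sContact contact-minimum width, A.
#' @slot aCore repulsive-core coefficient (r^-12), kcal/mol A^12.
#' @export
setClass("DynamicSSParams", representation(
  dBond = "numeric", rBond = "numeric", sBond = "numeric",
  dContact = "numeric", rContact = "numeric", sContact = "numeric",
  aCore = "numeric"
))

setValidity("DynamicSSParams", function(object) {
  msg <- character(0)
  if (!(object@dBond > object@dContact && object@dContact > 0))
    msg <- c(msg, "need dBond > dContact > 0")
  if (object@rContact <= object@rBond)
    msg <- c(msg, "need rContact > rBond")
  if (length(msg)) msg else TRUE
})

#' Triplet repulsion parameters
#'
#' Penalty preventing one cysteine from bonding two partners at once.  The
#' functional form used here is \eqn{a (s(r_{ki}) s(r_{kj}))^b} with the
#' logistic switch \eqn{s(r) = 1/(1+\exp((r-c)/d))}: it is nonnegative,
#' symmetric, and vanishes as soon as either partner distance leaves bonding
#' range.  All four parameters are user-tunable.
#'
#' @slot a penalty height, kcal/mol (default exceeds twice the deep bonded
#'   well so a double bond is always energetically forbidden).
#' @slot b product exponent.
#' @slot c switch distance, A.
#' @slot d switch softness, A.
#' @export
setClass("TripletParams", representation(
  a = "numeric", b = "numeric", c = "numeric", d = "numeric"
))

#' Flat-bottom breaking-restraint parameters
#'
#' Piecewise potential: harmonic below \code{r1}, zero on [r1, r2], harmonic
#' on [r2, r3], and linear above \code{r3} so that the restraint exerts the
#' constant force 2 k (r3 - r2) in the tail.
#'
#' @slot k spring constant, kcal/mol/A^2.
#' @slot r1,r2,r3 switching distances, A.
#' @export
setClass("RestraintParams", representation(
  k = "numeric", r1 = "numeric", r2 = "numeric", r3 = "numeric"
))

setValidity("RestraintParams", function(object) {
  if (!(object@r1 < object@r2 && object@r2 < object@r3))
    return("need r1 < r2 < r3")
  if (object@k <= 0) return("k must be > 0")
  TRUE
})

#' Redox model: how disulfide bonds are treated
#'
#' @slot mode one of \code{"none"} (reductive environment, no SS terms),
#'   \code{"dynamic"} (double-well over all cysteine pairs plus triplet
#'   repulsion; bonds can break and form), \code{"static"} (native crosslinks
#'   as permanent harmonic bonds) or \code{"restraint"} (flat-bottom breaking
#'   restraint on native crosslinks only).
#' @slot dynamic DynamicSSParams.
#' @slot triplet TripletParams.
#' @slot restraint RestraintParams.
#' @slot staticK spring constant for static bonds, kcal/mol/A^2.
#' @export
setClass("RedoxModel", representation(
  mode = "character", dynamic = "DynamicSSParams",
  triplet = "TripletParams", restraint = "RestraintParams",
  staticK = "numeric"
))

setValidity("RedoxModel", function(object) {
  if (!object@mode %in% c("none", "dynamic", "static", "restraint"))
    return("mode must be none/dynamic/static/restraint")
  TRUE
})

#' Steered-pulling protocol
#'
#' @slot speed pulling speed in Angstrom per MTU (1 MTU = 4.89 fs).
#' @slot springK pulling spring constant, kcal/mol/A^2 (force = k x).
#' @slot anchors length-2 integer of anchor residues (0-based); empty to use
#'   the topology anchors.
#' @slot temperature thermostat temperature, K.
#' @slot frictionScale dimensionless scaling of the base friction (default
#'   1/100, speeding up coarse-grained kinetics).
#' @slot frictionBase base Langevin friction, fs^-1.
#' @slot dt time step, fs.
#' @slot nSteps number of pulling steps.
#' @slot saveEvery save interval in steps.
#' @slot seed integer seed; identical protocol + seed give identical
#'   trajectories.
#' @slot minimizeSteps,thermalizeSteps preparation lengths.
#' @export
setClass("SMDProtocol", representation(
  speed = "numeric", springK = "numeric", anchors = "integer",
  temperature = "numeric", frictionScale = "numeric",
  frictionBase = "numeric", dt = "numeric", nSteps = "integer",
  saveEvery = "integer", seed = "integer",
  minimizeSteps = "integer", thermalizeSteps = "integer"
))

setValidity("SMDProtocol", function(object) {
  msg <- character(0)
  if (object@speed < 0) msg <- c(msg, "speed must be >= 0")
  if (object@springK <= 0) msg <- c(msg, "spring constant must be > 0")
  if (object@saveEvery < 1) msg <- c(msg, "save interval must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A steered (or equilibrium) trajectory with force and bond bookkeeping
#'
#' @slot log data.frame with one row per saved frame: \code{frame},
#'   \code{step}, \code{time_fs}, \code{extension_A}, \code{force_pN},
#'   \code{epot}, \code{ekin}.
#' @slot pairs data.frame of monitored cysteine pairs (1-based residues
#'   \code{resi}, \code{resj}, flag \code{native}).
#' @slot pairDist matrix (frames x pairs) of side-center distances, A.
#' @slot bonded logical matrix of debounced bond states (5.5 A criterion with
#'   2-frame hysteresis).
#' @slot events data.frame of bond events: \code{resi}, \code{resj},
#'   \code{kind} ("break"/"form"), \code{step}, \code{extension_A}.
#' @slot coords saved coordinates, array 3 x nBeads x nFrames (or empty).
#' @slot mode redox mode of the run.
#' @slot seed seed used.
#' @export
setClass("SMDTrajectory", representation(
  log = "data.frame", pairs = "data.frame", pairDist = "matrix",
  bonded = "matrix", events = "data.frame", coords = "array",
  mode = "character", seed = "integer"
))

#' Binned force-extension profile
#'
#' Mean pulling force and its standard error in 1 A extension bins, pooled
#' over all observations of all trajectories.  Only populated bins are kept.
#'
#' @slot profile data.frame: \code{bin_lo}, \code{bin_hi}, \code{mid},
#'   \code{n}, \code{mean_force_pN}, \code{sem_pN}.
#' @slot binWidth bin width, A.
#' @export
setClass("ForceExtensionProfile", representation(
  profile = "data.frame", binWidth = "numeric"
))

setValidity("ForceExtensionProfile", function(object) {
  p <- object@profile
  if (nrow(p) > 0 && any(p$n <= 0)) return("empty bins must be absent, not zero")
  TRUE
})
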
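# Constructors, accessors and show methods.

#' @rdname GoParams-class
#' @param bondK,bondB0,scBondK,epsContact,sigmaEV,sigmaEVSide,kEV,dihedralK,contactCutoff
#'   see the class slots.
#' @return a \code{GoParams} object.
#' @export
GoParams <- function(bondK = 100, bondB0 = 3.8, scBondK = 100,
                     epsContact = 1.0, sigmaEV = 4.0, sigmaEVSide = 3.0,
                     kEV = 5.0, dihedralK = 0.3, contactCutoff = 7.5) {
  new("GoParams", bondK = bondK, bondB0 = bondB0, scBondK = scBondK,
      epsContact = epsContact, sigmaEV = sigmaEV, sigmaEVSide = sigmaEVSide,
      kEV = kEV, dihedralK = dihedralK, contactCutoff = contactCutoff)
}

#' @rdname DynamicSSParams-class
#' @param dBond,rBond,sBond,dContact,rContact,sContact,aCore see the class
#'   slots.  \code{dBond = 5.5} models a weakly oxidizing and
#'   \code{dBond = 11.0} a highly oxidizing environment.
#' @return a \code{DynamicSSParams} object.
#' @export
DynamicSSParams <- function(dBond = 5.5, rBond = 4.0, sBond = 0.4,
                            dContact = 1.0, rContact = 6.5, sContact = 0.8,
                            aCore = 1e5) {
  new("DynamicSSParams", dBond = dBond, rBond = rBond, sBond = sBond,
      dContact = dContact, rContact = rContact, sContact = sContact,
      aCore = aCore)
}

#' @rdname TripletParams-class
#' @param a,b,c,d see the class slots.
#' @return a \code{TripletParams} object.
#' @export
TripletParams <- function(a = 30, b = 1, c = 5.5, d = 0.3) {
  new("TripletParams", a = a, b = b, c = c, d = d)
}

#' @rdname RestraintParams-class
#' @param k,r1,r2,r3 see the class slots.  Defaults are the published
#'   restraint constants for sulfur-sulfur distances.
#' @return a \code{RestraintParams} object.
#' @export
RestraintParams <- function(k = 4.0, r1 = 1.8, r2 = 3.0, r3 = 4.0) {
  new("RestraintParams", k = k, r1 = r1, r2 = r2, r3 = r3)
}

#' @rdname RedoxModel-class
#' @param mode bond treatment mode.
#' @param dynamic,triplet,restraint,staticK parameter sets.  When
#'   \code{mode = "restraint"} the default switch distances are shifted to
#'   2.8/4.0/5.0 A so that the flat region brackets the coarse-grained
#'   side-center bonded distance (4.0 A) instead of the all-atom S-S
#'   distance; the tail width r3 - r2, and hence the constant tail force,
#'   is unchanged.
#' @return a \code{RedoxModel} object.
#' @export
RedoxModel <- function(mode = c("dynamic", "none", "static", "restraint"),
                       dynamic = DynamicSSParams(),
                       triplet = TripletParams(),
                       restraint = NULL, staticK = 100) {
  mode <- match.arg(mode)
  if (is.null(restraint)) {
    restraint <- if (mode == "restraint")
      RestraintParams(k = 4.0, r1 = 2.8, r2 = 4.0, r3 = 5.0)
    else RestraintParams()
  }
  new("RedoxModel", mode = mode, dynamic = dynamic, triplet = triplet,
      restraint = restraint, staticK = staticK)
}

#' @rdname SMDProtocol-class
#' @param speed,springK,anchors,temperature,frictionScale,frictionBase,dt,nSteps,saveEvery,seed,minimizeSteps,thermalizeSteps
#'   see the class slots.
#' @return an \code{SMDProtocol} object.
#' @export
SMDProtocol <- function(speed = 0.02, springK = 1.0, anchors = integer(0),
                        temperature = 300, frictionScale = 0.01,
                        frictionBase = 5e-3, dt = 0.489, nSteps = 100000L,
                        saveEvery = 200L, seed = 1L,
                        minimizeSteps = 1000L, thermalizeSteps = 10000L) {
  new("SMDProtocol", speed = speed, springK = springK,
      anchors = as.integer(anchors), temperature = temperature,
      frictionScale = frictionScale, frictionBase = frictionBase, dt = dt,
      nSteps = as.integer(nSteps), saveEvery = as.integer(saveEvery),
      seed = as.integer(seed), minimizeSteps = as.integer(minimizeSteps),
      thermalizeSteps = as.integer(thermalizeSteps))
}

#' @rdname ToyFoldSpec-class
#' @param nResidues chain length.
#' @param blocks data.frame with columns \code{type} and \code{length};
#'   defaults to a single loop block spanning the chain.
#' @param crosslinks two-column matrix (or vector pairs) of 0-based residues.
#' @param seed integer seed.
#' @return a \code{ToyFoldSpec} object.
#' @export
ToyFoldSpec <- function(nResidues, blocks = NULL, crosslinks = NULL,
                        seed = 1L) {
  if (is.null(blocks))
    blocks <- data.frame(type = "loop", length = nResidues)
  if (is.null(crosslinks)) crosslinks <- matrix(integer(0), ncol = 2)
  crosslinks <- matrix(as.integer(crosslinks), ncol = 2)
  new("ToyFoldSpec", nResidues = as.integer(nResidues),
      blocks = data.frame(type = as.character(blocks$type),
                          length = as.integer(blocks$length)),
      crosslinks = crosslinks, seed = as.integer(seed))
}

#' Ribonuclease-A-like toy fold specification
#'
#' A synthetic 124-residue mimic of the RNase A architecture: three
#' helix-like and seven sheet-like blocks connected by loops, with the four
#' native crosslinks Cys26-Cys84, Cys40-Cys95, Cys58-Cys110 and Cys65-Cys72
#' (0-based: 25-83, 39-94, 57-109, 64-71).  This is a synthetic stand-in for
#' the experimental structure, not the crystallographic fold.
#'
#' @param seed integer seed.
#' @return a \code{ToyFoldSpec}.
#' @export
rnaseMimicSpec <- function(seed = 1L) {
  blocks <- data.frame(
    type = c("loop", "helix", "loop", "helix", "loop", "sheet", "loop",
             "helix", "sheet", "loop", "sheet", "loop", "sheet", "loop",
             "sheet", "loop", "sheet", "loop", "sheet", "loop"),
    length = c(2, 11, 10, 10, 9, 5, 2, 11, 3, 8, 3, 4, 8, 10, 8, 1, 6, 4,
               8, 1))
  ToyFoldSpec(124L, blocks,
              crosslinks = rbind(c(25L, 83L), c(39L, 94L),
                                 c(57L, 109L), c(64L, 71L)),
              seed = seed)
}

# ---- accessors -------------------------------------------------------------

#' Number of residues
#' @param x a ChainTopology.
#' @return integer count.
#' @export
nResidues <- function(x) x@nResidues

#' Native coordinates of a topology
#' @param x a ChainTopology.
#' @return numeric matrix (nBeads x 3).
#' @export
nativeCoords <- function(x) x@nativeCoords

#' Cysteine residues (1-based)
#' @param x a ChainTopology.
#' @return integer vector of residue numbers.
#' @export
cysteines <- function(x) x@cysteines + 1L

#' Native crosslink pairs (1-based)
#' @param x a ChainTopology.
#' @return two-column integer matrix.
#' @export
crosslinks <- function(x) x@crosslinks + 1L

#' Pulling anchors (1-based)
#' @param x a ChainTopology.
#' @return length-2 integer vector.
#' @export
anchors <- function(x) x@anchors + 1L

#' Native contacts
#' @param x a ChainTopology.
#' @return data.frame with 1-based residue columns, native distance and
#'   element label.
#' @export
nativeContacts <- function(x) {
  nc <- x@nativeContacts
  data.frame(i = nc$i + 1L, j = nc$j + 1L, r0 = nc$r0, element = nc$element)
}

#' Trajectory log
#' @param x an SMDTrajectory.
#' @return data.frame of per-frame observables.
#' @export
trajectoryLog <- function(x) x@log

#' Bond events of a trajectory
#' @param x an SMDTrajectory.
#' @return data.frame of break/form events (1-based residues).
#' @export
bondEvents <- function(x) x@events

# ---- show methods ----------------------------------------------------------

setMethod("show", "ChainTopology", function(object) {
  cat("ChainTopology:", object@nResidues, "residues,",
      nrow(object@beads), "beads\n")
  cat("  native contacts:", nrow(object@nativeContacts),
      " elements:", length(unique(object@elements$element)), "\n")
  cys <- object@cysteines + 1L
  cat("  cysteines (1-based):", if (length(cys)) paste(cys, collapse = ", ")
      else "none", "\n")
  if (nrow(object@crosslinks) > 0) {
    xl <- object@crosslinks + 1L
    cat("  crosslinks:", paste(sprintf("%d-%d", xl[, 1], xl[, 2]),
                               collapse = ", "), "\n")
  }
  cat("  anchors (1-based):", paste(object@anchors + 1L, collapse = ", "),
      "\n")
})

setMethod("show", "RedoxModel", function(object) {
  cat("RedoxModel, mode =", object@mode, "\n")
  if (object@mode == "dynamic")
    cat(sprintf("  double well: D_bond = %.2f kcal/mol at %.2f A, contact %.2f at %.2f A\n",
                object@dynamic@dBond, object@dynamic@rBond,
                object@dynamic@dContact, object@dynamic@rContact))
  if (object@mode == "restraint")
    cat(sprintf("  flat bottom: k = %.2f, r1/r2/r3 = %.2f/%.2f/%.2f A (tail force %.1f pN)\n",
                object@restraint@k, object@restraint@r1, object@restraint@r2,
                object@restraint@r3,
                2 * object@restraint@k *
                  (object@restraint@r3 - object@restraint@r2) * .pNperKcalMolA))
})

setMethod("show", "SMDProtocol", function(object) {
  cat(sprintf("SMDProtocol: speed %.4g A/MTU (%.3g m/s reported), spring %.3g kcal/mol/A^2\n",
              object@speed, signif(cgSpeedToMps(object@speed), 2),
              object@springK))
  cat(sprintf("  T = %g K, dt = %g fs, %d steps, save every %d, seed %d\n",
              object@temperature, object@dt, object@nSteps, object@saveEvery,
              object@seed))
})

setMethod("show", "SMDTrajectory", function(object) {
  cat("SMDTrajectory (mode =", object@mode, "):", nrow(object@log),
      "frames\n")
  if (nrow(object@log) > 0)
    cat(sprintf("  extension %.1f .. %.1f A, max |force| %.1f pN\n",
                min(object@log$extension_A), max(object@log$extension_A),
                max(abs(object@log$force_pN))))
  cat("  bond events:", nrow(object@events), "\n")
})

setMethod("show", "ForceExtensionProfile", function(object) {
  cat("ForceExtensionProfile:", nrow(object@profile), "populated bins of",
      object@binWidth, "A\n")
  if (nrow(object@profile) > 0) {
    i <- which.max(object@profile$mean_force_pN)
    cat(sprintf("  max mean force %.1f pN at %.1f A\n",
                object@profile$mean_force_pN[i], object@profile$mid[i]))
  }
})
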
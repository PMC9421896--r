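# Internal: translate a ChainTopology + parameter sets into the flat system
# description consumed by the compiled engine.  Bead indices are 0-based on
# this boundary.

.modeCode <- c(none = 0L, dynamic = 1L, static = 2L, restraint = 3L)

# side-center bead index per residue (NA where absent), 0-based
.scBeadMap <- function(topology) {
  m <- rep(NA_integer_, topology@nResidues)
  sc <- topology@beads[topology@beads$kind == "sc", ]
  m[sc$residue + 1L] <- sc$bead
  m
}

.ssBeadForResidue <- function(topology, residues) {
  m <- .scBeadMap(topology)
  b <- m[residues + 1L]
  if (anyNA(b)) stop("cysteine residue without side-center bead")
  b
}

# pairs monitored in the force log: all cysteine pairs (dynamic/none),
# crosslinks only (static/restraint)
.monitorPairs <- function(topology, mode) {
  cys <- topology@cysteines
  if (mode %in% c("static", "restraint") || length(cys) < 2) {
    xl <- topology@crosslinks
    if (nrow(xl) == 0) return(data.frame(resi = integer(0), resj = integer(0),
                                         native = logical(0)))
    return(data.frame(resi = xl[, 1], resj = xl[, 2], native = TRUE))
  }
  prs <- t(combn(sort(cys), 2))
  nat <- apply(prs, 1, function(p) {
    any(topology@crosslinks[, 1] == min(p) & topology@crosslinks[, 2] == max(p) |
        topology@crosslinks[, 1] == max(p) & topology@crosslinks[, 2] == min(p))
  })
  if (nrow(topology@crosslinks) == 0) nat <- rep(FALSE, nrow(prs))
  data.frame(resi = prs[, 1], resj = prs[, 2], native = nat)
}

.dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  y <- sum(m * b2) / sqrt(sum(b2^2))
  atan2(y, sum(n1 * n2))
}

# Build the engine system list.  nativeCoords is used for dihedral reference
# angles.  ssActive pairs are excluded from excluded volume.
.buildSystem <- function(topology, go, redox, nativeCoords = NULL,
                         tethers = NULL, moving = NULL) {
  if (is.null(nativeCoords)) nativeCoords <- topology@nativeCoords
  beads <- topology@beads
  nb <- nrow(beads)
  mode <- redox@mode

  bonds <- rbind(
    if (nrow(topology@backboneBonds) > 0)
      cbind(topology@backboneBonds$i, topology@backboneBonds$j,
            topology@backboneBonds$b0, go@bondK),
    if (nrow(topology@sideBonds) > 0)
      cbind(topology@sideBonds$i, topology@sideBonds$j,
            topology@sideBonds$b0, go@scBondK))
  if (is.null(bonds)) bonds <- matrix(0, 0, 4)

  # static mode: crosslinks become permanent harmonic bonds between SC beads
  if (mode == "static" && nrow(topology@crosslinks) > 0) {
    b1 <- .ssBeadForResidue(topology, topology@crosslinks[, 1])
    b2 <- .ssBeadForResidue(topology, topology@crosslinks[, 2])
    bonds <- rbind(bonds, cbind(b1, b2, redox@dynamic@rBond, redox@staticK))
  }

  contacts <- if (nrow(topology@nativeContacts) > 0)
    cbind(topology@nativeContacts$i, topology@nativeContacts$j,
          topology@nativeContacts$r0, go@epsContact)
  else matrix(0, 0, 4)

  # pseudo-dihedrals over consecutive backbone beads
  n <- topology@nResidues
  dihedrals <- matrix(0, 0, 6)
  if (n >= 4 && go@dihedralK > 0) {
    idx <- seq_len(n - 3) - 1L
    phi0 <- vapply(idx, function(i) {
      .dihedralAngle(nativeCoords[i + 1, ], nativeCoords[i + 2, ],
                     nativeCoords[i + 3, ], nativeCoords[i + 4, ])
    }, numeric(1))
    dihedrals <- cbind(idx, idx + 1L, idx + 2L, idx + 3L, phi0, go@dihedralK)
  }

  # SS-active side-center pairs (these carry their own interaction)
  cysBeads <- if (length(topology@cysteines) > 0)
    .ssBeadForResidue(topology, sort(topology@cysteines)) else integer(0)
  ssPairs <- matrix(0L, 0, 2)
  if (mode == "dynamic" && length(cysBeads) >= 2)
    ssPairs <- t(combn(cysBeads, 2))
  restPairs <- matrix(0L, 0, 2)
  if (mode == "restraint") {
    if (nrow(topology@crosslinks) == 0)
      stop("restraint mode requires a non-empty crosslink list")
    restPairs <- cbind(.ssBeadForResidue(topology, topology@crosslinks[, 1]),
                       .ssBeadForResidue(topology, topology@crosslinks[, 2]))
  }
  ssActive <- ssPairs
  if (mode %in% c("static", "restraint") && nrow(topology@crosslinks) > 0)
    ssActive <- cbind(.ssBeadForResidue(topology, topology@crosslinks[, 1]),
                      .ssBeadForResidue(topology, topology@crosslinks[, 2]))

  ev <- .buildEVPairs(topology, go, contacts, ssActive)

  sys <- list(
    mass = rep(.beadMassAmu * .massUnit, nb),
    bonds = bonds, contacts = contacts, evPairs = ev, dihedrals = dihedrals,
    ssMode = unname(.modeCode[mode]), ssPairs = ssPairs,
    cysBeads = as.integer(cysBeads), restPairs = restPairs,
    dynPar = c(redox@dynamic@aCore, redox@dynamic@dBond, redox@dynamic@rBond,
               redox@dynamic@sBond, redox@dynamic@dContact,
               redox@dynamic@rContact, redox@dynamic@sContact),
    tripletPar = c(redox@triplet@a, redox@triplet@b, redox@triplet@c,
                   redox@triplet@d),
    restPar = c(redox@restraint@k, redox@restraint@r1, redox@restraint@r2,
                redox@restraint@r3),
    tethers = if (is.null(tethers)) matrix(0, 0, 5) else tethers,
    moving = moving,
    anchorA = 0L, anchorB = 0L, nativeDist = 0)
  anc <- topology@anchors
  if (length(anc) == 2) {
    sys$anchorA <- anc[1]           # backbone bead index == residue ordinal
    sys$anchorB <- anc[2]
    sys$nativeDist <- sqrt(sum((nativeCoords[anc[2] + 1, ] -
                                nativeCoords[anc[1] + 1, ])^2))
  }
  sys
}

# excluded-volume pair list: backbone pairs separated by >= 2 residues that
# are not native contacts, plus side-center pairs that carry no explicit
# interaction of their own.
.buildEVPairs <- function(topology, go, contacts, ssActive) {
  beads <- topology@beads
  n <- topology@nResidues
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  skip <- character(0)
  if (nrow(contacts) > 0) skip <- c(skip, key(contacts[, 1], contacts[, 2]))
  if (nrow(ssActive) > 0) skip <- c(skip, key(ssActive[, 1], ssActive[, 2]))
  skip <- unique(skip)

  mk <- function(i, j, sigma, k) {
    if (length(i) == 0) return(NULL)
    cbind(i, j, rep(sigma, length(i)), rep(k, length(i)))
  }
  out <- vector("list", 3)
  # bb-bb
  if (n >= 3) {
    prs <- t(combn(seq_len(n) - 1L, 2))
    prs <- prs[prs[, 2] - prs[, 1] >= 2, , drop = FALSE]
    keep <- !(key(prs[, 1], prs[, 2]) %in% skip)
    out[[1]] <- mk(prs[keep, 1], prs[keep, 2], go@sigmaEV, go@kEV)
  }
  sc <- beads[beads$kind == "sc", ]
  if (nrow(sc) > 0) {
    # sc-bb (different residue)
    grid <- expand.grid(s = seq_len(nrow(sc)), r = seq_len(n) - 1L)
    grid <- grid[sc$residue[grid$s] != grid$r, ]
    p1 <- sc$bead[grid$s]; p2 <- grid$r
    keep <- !(key(p1, p2) %in% skip)
    out[[2]] <- mk(pmin(p1, p2)[keep], pmax(p1, p2)[keep],
                   go@sigmaEVSide, go@kEV)
    # sc-sc
    if (nrow(sc) >= 2) {
      prs <- t(combn(sc$bead, 2))
      keep <- !(key(prs[, 1], prs[, 2]) %in% skip)
      out[[3]] <- mk(prs[keep, 1], prs[keep, 2], go@sigmaEVSide, go@kEV)
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev)) matrix(0, 0, 4) else ev
}
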
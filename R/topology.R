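# Topology generation: synthetic crosslinked toy folds, PDB-derived
# topologies, disulfide detection and the contour-length extension bound.

.elementLabels <- function(blocks) {
  counts <- c(helix = 0L, sheet = 0L, loop = 0L)
  labs <- character(nrow(blocks))
  for (k in seq_len(nrow(blocks))) {
    ty <- blocks$type[k]
    counts[ty] <- counts[ty] + 1L
    labs[k] <- paste0(switch(ty, helix = "H", sheet = "B", loop = "L"),
                      counts[ty])
  }
  labs
}

# Raw backbone placement: secondary-structure blocks become vertical columns
# on a serpentine 2D grid (helix = 1.5 A rise spiral, sheet = 3.3 A rise
# strand); loop blocks arc between consecutive columns.  Deterministic apart
# from a small seeded jitter that breaks planar symmetries.
.placeBackbone <- function(blocks) {
  n <- sum(blocks$length)
  coords <- matrix(NA_real_, n, 3)
  colIdx <- which(blocks$type != "loop")
  ncol_ <- length(colIdx)
  W <- max(1L, ceiling(sqrt(ncol_)))
  dx <- 5.0; dy <- 5.5
  colXY <- matrix(0, max(ncol_, 1), 2)
  for (c in seq_len(ncol_)) {
    r0 <- (c - 1) %/% W
    pos <- (c - 1) %% W
    if (r0 %% 2 == 1) pos <- W - 1 - pos
    colXY[c, ] <- c(dx * pos, dy * r0)
  }
  res0 <- cumsum(c(0, blocks$length))  # start residue (0-based) per block
  dir <- 1
  zEnd <- 0
  lastPoint <- NULL
  colNo <- 0L
  k <- 1
  while (k <= nrow(blocks)) {
    len <- blocks$length[k]
    i0 <- res0[k] + 1          # 1-based row index into coords
    if (blocks$type[k] != "loop") {
      colNo <- colNo + 1L
      xy <- colXY[colNo, ]
      rise <- if (blocks$type[k] == "helix") 1.5 else 3.3
      t <- seq_len(len) - 1
      z <- zEnd + dir * rise * t
      if (blocks$type[k] == "helix") {
        ang <- 1.745 * t + 0.3 * colNo
        x <- xy[1] + 2.3 * cos(ang)
        y <- xy[2] + 2.3 * sin(ang)
      } else {
        x <- xy[1] + 0.6 * (-1)^t
        y <- xy[2] + rep(0, len)
      }
      coords[i0:(i0 + len - 1), ] <- cbind(x, y, z)
      zEnd <- z[len]
      lastPoint <- coords[i0 + len - 1, ]
      dir <- -dir
    } else {
      # loop: connect lastPoint to the start of the next column (or run
      # straight when the chain starts/ends with a loop)
      nxt <- which(blocks$type != "loop" & seq_len(nrow(blocks)) > k)
      if (is.null(lastPoint) && length(nxt) > 0) {
        # leading loop: straight approach to the first column
        xy <- colXY[colNo + 1L, ]
        B <- c(xy[1] + 2.3, xy[2], zEnd)
        for (t in seq_len(len))
          coords[i0 + t - 1, ] <- B - c(3.3 * (len - t + 1), 0, 0)
      } else if (length(nxt) > 0) {
        xy <- colXY[colNo + 1L, ]
        B <- c(xy[1] + if (blocks$type[nxt[1]] == "helix") 2.3 else 0.6,
               xy[2], zEnd)
        A <- lastPoint
        d <- B - A
        bulgeDir <- c(0, 0, -dir)   # arc continues past the previous column
        need <- 3.4 * (len + 1) - sqrt(sum(d^2))
        h <- min(8, max(1.5, 0.6 * need))
        for (t in seq_len(len)) {
          s <- t / (len + 1)
          coords[i0 + t - 1, ] <- A + s * d + h * sin(pi * s) * bulgeDir
        }
      } else {
        # trailing loop: extend away from the fold
        A <- if (is.null(lastPoint)) c(0, 0, 0) else lastPoint
        for (t in seq_len(len))
          coords[i0 + t - 1, ] <- A + c(3.3 * t, 0, 0)
        lastPoint <- coords[i0 + len - 1, ]
      }
      if (len > 0 && !is.null(lastPoint)) lastPoint <- coords[i0 + len - 1, ]
    }
    k <- k + 1
  }
  coords
}

.minNonbondedDistance <- function(topology, coords) {
  nb <- nrow(coords)
  bonded <- rbind(as.matrix(topology@backboneBonds[, c("i", "j")]),
                  as.matrix(topology@sideBonds[, c("i", "j")]))
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (nrow(bonded) > 0) {
    d[cbind(bonded[, 1] + 1, bonded[, 2] + 1)] <- Inf
    d[cbind(bonded[, 2] + 1, bonded[, 1] + 1)] <- Inf
  }
  min(d)
}

.contactsFromCoords <- function(coords, n, cutoff, elements) {
  d <- as.matrix(stats::dist(coords[seq_len(n), , drop = FALSE]))
  prs <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  prs <- prs[abs(prs[, 1] - prs[, 2]) >= 3, , drop = FALSE]
  if (nrow(prs) == 0)
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                      element = character(0)))
  i <- pmin(prs[, 1], prs[, 2]) - 1L
  j <- pmax(prs[, 1], prs[, 2]) - 1L
  ei <- elements[i + 1]; ej <- elements[j + 1]
  lab <- ifelse(ei == ej, ei, paste(pmin(ei, ej), pmax(ei, ej), sep = "|"))
  data.frame(i = i, j = j, r0 = d[cbind(i + 1, j + 1)], element = lab)
}

#' Generate a synthetic crosslinked toy fold
#'
#' Builds a compact, self-avoiding folded conformation from the block layout
#' of a \code{\link{ToyFoldSpec}}: blocks are placed as secondary-structure
#' columns on a serpentine grid, cysteine side-centers are added, crosslink
#' pairs are drawn together by restrained minimization, native contacts are
#' computed from the built coordinates, and the structure is relaxed to a
#' minimum of the resulting structure-based potential.  Identical spec and
#' seed give bitwise-identical output.
#'
#' @param spec a \code{ToyFoldSpec}.
#' @param go \code{GoParams} for the background potential.
#' @param rBond bonded-well position used for crosslink restraints, A.
#' @return a \code{ChainTopology} whose \code{nativeCoords} slot holds the
#'   relaxed native conformation.
#' @examples
#' top <- generateToyFold(ToyFoldSpec(20))
#' nResidues(top)
#' @export
generateToyFold <- function(spec, go = GoParams(), rBond = 4.0) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nResidues
  blocks <- spec@blocks
  labs <- .elementLabels(blocks)
  elements <- rep(labs, blocks$length)

  coords <- .placeBackbone(blocks)
  coords <- coords + matrix(rnorm(3 * n, sd = 0.05), n, 3)

  cys <- sort(unique(as.integer(spec@crosslinks)))
  resname <- rep("GLY", n)
  resname[cys + 1] <- "CYS"

  # side-center beads for cysteines, initially offset toward the partner
  scBead <- integer(0); scRes <- integer(0)
  scCoords <- NULL
  partner <- rep(NA_integer_, n)
  if (nrow(spec@crosslinks) > 0) {
    partner[spec@crosslinks[, 1] + 1] <- spec@crosslinks[, 2]
    partner[spec@crosslinks[, 2] + 1] <- spec@crosslinks[, 1]
  }
  for (r in cys) {
    dirv <- if (!is.na(partner[r + 1]))
      coords[partner[r + 1] + 1, ] - coords[r + 1, ] else c(0, 1, 0)
    nv <- sqrt(sum(dirv^2)); if (nv < 1e-8) dirv <- c(0, 1, 0) else dirv <- dirv / nv
    scBead <- c(scBead, n + length(scRes))
    scRes <- c(scRes, r)
    scCoords <- rbind(scCoords, coords[r + 1, ] + .scBondLength * dirv)
  }
  beads <- rbind(
    data.frame(bead = seq_len(n) - 1L, residue = seq_len(n) - 1L,
               kind = "bb", resname = resname),
    if (length(scRes) > 0)
      data.frame(bead = scBead, residue = scRes, kind = "sc",
                 resname = resname[scRes + 1]))
  allCoords <- rbind(coords, scCoords)

  top <- new("ChainTopology", nResidues = n, beads = beads,
             backboneBonds = if (n > 1)
               data.frame(i = 0:(n - 2), j = 1:(n - 1), b0 = go@bondB0)
             else data.frame(i = integer(0), j = integer(0), b0 = numeric(0)),
             sideBonds = if (length(scRes) > 0)
               data.frame(i = scRes, j = scBead, b0 = .scBondLength)
             else data.frame(i = integer(0), j = integer(0), b0 = numeric(0)),
             nativeContacts = data.frame(i = integer(0), j = integer(0),
                                         r0 = numeric(0),
                                         element = character(0)),
             cysteines = as.integer(cys), crosslinks = spec@crosslinks,
             anchors = if (n >= 4) c(1L, n - 2L) else c(0L, n - 1L),
             nativeCoords = allCoords,
             cbeta = matrix(NA_real_, 0, 3),
             elements = data.frame(residue = seq_len(n) - 1L,
                                   element = elements))

  redoxNone <- RedoxModel("none")
  scMap <- .scBeadMap(top)

  # keep non-crosslinked cysteine side-centers apart while building the
  # native fold, so the native structure carries no non-native SS contacts
  scBeadsAll <- scMap[!is.na(scMap)]
  natKey <- if (nrow(spec@crosslinks) > 0)
    paste(pmin(scMap[spec@crosslinks[, 1] + 1], scMap[spec@crosslinks[, 2] + 1]),
          pmax(scMap[spec@crosslinks[, 1] + 1], scMap[spec@crosslinks[, 2] + 1]))
  else character(0)
  .spreadNonNative <- function(sys) {
    if (length(scBeadsAll) < 2) return(sys)
    ev <- sys$evPairs
    isSC <- ev[, 1] %in% scBeadsAll & ev[, 2] %in% scBeadsAll
    isNat <- paste(ev[, 1], ev[, 2]) %in% natKey
    ev[isSC & !isNat, 3] <- 6.0
    sys$evPairs <- ev
    sys
  }

  # stage 1: bonds + excluded volume + harmonic crosslink restraints
  stage1 <- function(kRestraint, start, maxSteps) {
    sys <- .spreadNonNative(.buildSystem(top, go, redoxNone,
                                         nativeCoords = start))
    if (nrow(spec@crosslinks) > 0) {
      b1 <- scMap[spec@crosslinks[, 1] + 1]
      b2 <- scMap[spec@crosslinks[, 2] + 1]
      sys$bonds <- rbind(sys$bonds, cbind(b1, b2, rBond, kRestraint))
      # crosslinked side-center pairs must not collide with excluded volume
      drop <- (sys$evPairs[, 1] %in% b1 & sys$evPairs[, 2] %in% b2) |
              (sys$evPairs[, 1] %in% b2 & sys$evPairs[, 2] %in% b1)
      sys$evPairs <- sys$evPairs[!drop, , drop = FALSE]
    }
    sys$contacts <- matrix(0, 0, 4)
    sys$dihedrals <- matrix(0, 0, 6)
    engineMinimize(sys, start, maxSteps = maxSteps, fTol = 1e-3)$coords
  }
  x1 <- stage1(20, allCoords, 3000L)
  if (nrow(spec@crosslinks) > 0) {
    dxl <- .crosslinkDistances(top, x1)
    if (any(dxl >= 5.0)) x1 <- stage1(80, x1, 4000L)
    dxl <- .crosslinkDistances(top, x1)
    if (any(dxl >= 5.5)) {
      bad <- which(dxl >= 5.5)[1]
      stop(sprintf("crosslink spec unsatisfiable: pair %d-%d relaxes to %.1f A (>= 5.5 A)",
                   spec@crosslinks[bad, 1] + 1L, spec@crosslinks[bad, 2] + 1L,
                   dxl[bad]))
    }
  }

  # stage 2: native contacts from the built coordinates, then relax under the
  # full structure-based potential with crosslinks held
  top@nativeContacts <- .contactsFromCoords(x1, n, go@contactCutoff, elements)
  sysFull <- .spreadNonNative(.buildSystem(top, go, RedoxModel("static"),
                                           nativeCoords = x1))
  x2 <- engineMinimize(sysFull, x1, maxSteps = 4000L, fTol = 5e-4)$coords

  # final pass: contacts and dihedral references from the relaxed structure
  top@nativeContacts <- .contactsFromCoords(x2, n, go@contactCutoff, elements)
  sysFull <- .spreadNonNative(.buildSystem(top, go, RedoxModel("static"),
                                           nativeCoords = x2))
  x3 <- engineMinimize(sysFull, x2, maxSteps = 3000L, fTol = 2e-4)$coords
  top@nativeCoords <- x3

  if (nrow(spec@crosslinks) > 0) {
    dxl <- .crosslinkDistances(top, x3)
    if (any(dxl >= 5.5)) {
      bad <- which(dxl >= 5.5)[1]
      stop(sprintf("crosslink spec unsatisfiable: pair %d-%d relaxes to %.1f A (>= 5.5 A)",
                   spec@crosslinks[bad, 1] + 1L, spec@crosslinks[bad, 2] + 1L,
                   dxl[bad]))
    }
  }
  validObject(top)
  top
}

.crosslinkDistances <- function(topology, coords) {
  if (nrow(topology@crosslinks) == 0) return(numeric(0))
  scMap <- .scBeadMap(topology)
  b1 <- scMap[topology@crosslinks[, 1] + 1]
  b2 <- scMap[topology@crosslinks[, 2] + 1]
  sqrt(rowSums((coords[b1 + 1, , drop = FALSE] -
                coords[b2 + 1, , drop = FALSE])^2))
}

# Cbeta-proxy positions per residue for the bond-presence criterion:
# real Cbeta where available, side-center otherwise.
.ssProxyCoords <- function(topology, coords) {
  n <- topology@nResidues
  out <- matrix(NA_real_, n, 3)
  if (nrow(topology@cbeta) == n) out <- topology@cbeta
  scMap <- .scBeadMap(topology)
  fill <- which(is.na(out[, 1]) & !is.na(scMap))
  if (length(fill) > 0) out[fill, ] <- coords[scMap[fill] + 1, , drop = FALSE]
  out
}

#' Detect disulfide bonds from coordinates
#'
#' All cysteine pairs whose C-beta (or side-center proxy) distance is below
#' the cutoff, with each cysteine matched to at most one partner, greedily by
#' ascending distance.  The 5.5 A default is the standard bond-presence
#' criterion.
#'
#' @param topology a \code{ChainTopology}.
#' @param coords coordinates (defaults to the native conformation).
#' @param cutoff distance cutoff, A.
#' @return data.frame with 1-based residue columns \code{resi}, \code{resj}
#'   and \code{distance}.
#' @export
detectDisulfides <- function(topology, coords = nativeCoords(topology),
                             cutoff = 5.5) {
  cys <- sort(topology@cysteines)
  empty <- data.frame(resi = integer(0), resj = integer(0),
                      distance = numeric(0))
  if (length(cys) < 2) return(empty)
  pos <- .ssProxyCoords(topology, coords)[cys + 1, , drop = FALSE]
  prs <- t(combn(seq_along(cys), 2))
  d <- sqrt(rowSums((pos[prs[, 1], , drop = FALSE] -
                     pos[prs[, 2], , drop = FALSE])^2))
  ok <- which(d < cutoff)
  if (length(ok) == 0) return(empty)
  ord <- ok[order(d[ok])]
  used <- logical(length(cys))
  out <- empty
  for (q in ord) {
    a <- prs[q, 1]; b <- prs[q, 2]
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    out <- rbind(out, data.frame(resi = cys[a] + 1L, resj = cys[b] + 1L,
                                 distance = d[q]))
  }
  out[order(out$resi), , drop = FALSE]
}

#' Load a coarse-grained topology from a PDB structure
#'
#' One backbone bead per residue at the C-alpha position and one side-center
#' bead at the centroid of the side-chain heavy atoms; C-beta coordinates are
#' retained separately for the bond-presence criterion.  Where a residue has
#' alternate locations, the highest-occupancy altloc is kept (ties go to
#' altloc "A").  Residues without a C-alpha atom are rejected with a warning.
#'
#' @param pdb path to a PDB file, or a character vector of PDB record lines.
#' @param chain chain identifier; defaults to the first chain present.
#' @param go \code{GoParams} used for contact detection and bond lengths.
#' @return a \code{ChainTopology} with native coordinates.
#' @export
loadStructure <- function(pdb, chain = NULL, go = GoParams()) {
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
    on.exit(unlink(tf))
    pdb <- tf
  }
  p <- bio3d::read.pdb(pdb, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  # drop hydrogens
  at <- at[!grepl("^H|^[0-9]H", trimws(at$elety)), , drop = FALSE]
  if (nrow(at) == 0) stop("no residues found in PDB input")

  # altloc resolution: keep highest occupancy, ties -> altloc 'A'
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  keyv <- paste(at$resno, at$insert, trimws(at$elety))
  keep <- unlist(lapply(split(seq_len(nrow(at)), keyv), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$o[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1) {
      prefA <- best[at$alt[best] %in% c("A", "")]
      if (length(prefA) > 0) best <- prefA
    }
    best[1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  resKey <- paste(at$resno, at$insert)
  resOrder <- unique(resKey)
  bbCoords <- NULL; resname <- character(0)
  scList <- list(); cbList <- list()
  dropped <- 0L
  for (rk in resOrder) {
    rows <- at[resKey == rk, , drop = FALSE]
    ca <- rows[trimws(rows$elety) == "CA", , drop = FALSE]
    if (nrow(ca) == 0) { dropped <- dropped + 1L; next }
    bbCoords <- rbind(bbCoords, c(ca$x[1], ca$y[1], ca$z[1]))
    resname <- c(resname, trimws(ca$resid[1]))
    side <- rows[!trimws(rows$elety) %in% c("N", "CA", "C", "O", "OXT"), ,
                 drop = FALSE]
    scList[length(resname)] <- list(if (nrow(side) > 0)
      c(mean(side$x), mean(side$y), mean(side$z)) else NULL)
    cb <- rows[trimws(rows$elety) == "CB", , drop = FALSE]
    cbList[length(resname)] <- list(if (nrow(cb) > 0)
      c(cb$x[1], cb$y[1], cb$z[1]) else NULL)
  }
  if (dropped > 0)
    warning(sprintf("rejected %d residue(s) without a C-alpha atom", dropped))
  n <- length(resname)
  if (n == 0) stop("no residues with C-alpha atoms in PDB input")

  cbeta <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) if (!is.null(cbList[[i]])) cbeta[i, ] <- cbList[[i]]

  scRes <- which(!vapply(scList, is.null, logical(1), USE.NAMES = FALSE))
  scCoords <- do.call(rbind, scList[scRes])
  scBead <- n + seq_along(scRes) - 1L
  beads <- rbind(
    data.frame(bead = seq_len(n) - 1L, residue = seq_len(n) - 1L,
               kind = "bb", resname = resname),
    if (length(scRes) > 0)
      data.frame(bead = scBead, residue = scRes - 1L, kind = "sc",
                 resname = resname[scRes]))
  allCoords <- rbind(bbCoords, scCoords)
  sideB0 <- if (length(scRes) > 0)
    sqrt(rowSums((bbCoords[scRes, , drop = FALSE] - scCoords)^2))
  else numeric(0)

  cys <- which(resname %in% c("CYS", "CYX")) - 1L
  elements <- rep("body", n)
  top <- new("ChainTopology", nResidues = n, beads = beads,
             backboneBonds = if (n > 1)
               data.frame(i = 0:(n - 2), j = 1:(n - 1), b0 = go@bondB0)
             else data.frame(i = integer(0), j = integer(0), b0 = numeric(0)),
             sideBonds = data.frame(i = scRes - 1L, j = scBead, b0 = sideB0),
             nativeContacts = .contactsFromCoords(allCoords, n,
                                                  go@contactCutoff, elements),
             cysteines = as.integer(cys),
             crosslinks = matrix(integer(0), ncol = 2),
             anchors = if (n >= 4) c(1L, n - 2L) else c(0L, max(n - 1L, 1L)),
             nativeCoords = allCoords, cbeta = cbeta,
             elements = data.frame(residue = seq_len(n) - 1L,
                                   element = elements))
  ss <- detectDisulfides(top)
  if (nrow(ss) > 0)
    top@crosslinks <- cbind(ss$resi - 1L, ss$resj - 1L)
  validObject(top)
  top
}

#' Upper bound on anchor separation under inextensible links
#'
#' Shortest-path distance between the two anchors in the graph whose edges
#' are backbone bonds (weighted by their equilibrium length) and intact
#' crosslinks (weighted by the residue-level bonded distance: the side-center
#' bonded-well position plus the two side-center tether lengths).  This is
#' the supremum of the anchor separation while all links hold, and it is
#' monotone non-decreasing as crosslinks are removed from the intact set.
#'
#' @param topology a \code{ChainTopology}.
#' @param intact two-column matrix of intact crosslinks, 1-based residue
#'   numbers (pass \code{crosslinks(topology)} or a subset of its rows).
#'   Defaults to all native crosslinks.
#' @param crosslinkLength residue-level length of an intact crosslink, A.
#' @param anchors optional pair of 1-based residues; default the topology
#'   anchors.
#' @return length in A.
#' @export
maxExtensionBound <- function(topology, intact = crosslinks(topology),
                              crosslinkLength = 4.0 + 2 * .scBondLength,
                              anchors = NULL) {
  n <- topology@nResidues
  if (n < 2) stop("need at least two residues")
  anc1 <- if (is.null(anchors)) topology@anchors + 1L else as.integer(anchors)
  if (length(anc1) != 2 || any(anc1 < 1 | anc1 > n))
    stop("anchors must be two 1-based residues")
  intact <- matrix(as.integer(intact), ncol = 2)
  if (nrow(intact) > 0) {
    if (any(intact < 1 | intact > n)) stop("intact pairs must be 1-based residues")
    intact <- intact - 1L
  }
  bb <- topology@backboneBonds
  edges <- rbind(cbind(bb$i, bb$j), intact)
  w <- c(bb$b0, rep(crosslinkLength, nrow(intact)))
  g <- igraph::graph_from_edgelist(edges + 1L, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = anc1[1], to = anc1[2])[1, 1]
  if (!is.finite(d)) stop("anchor graph is disconnected")
  unname(d)
}
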
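# Text I/O: topology TSV bundles, PDB structures, XYZ trajectories and
# TSV force/event logs.  Every numeric table carries a header comment with
# the originating seed/config hash so outputs are traceable.

.writeHeader <- function(file, meta) {
  con <- file(file, "w")
  writeLines(sprintf("# %s", paste(names(meta), unlist(meta), sep = "=",
                                   collapse = " ")), con)
  close(con)
}

.appendTable <- function(df, file) {
  suppressWarnings(write.table(df, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
}

#' Write a topology as a TSV bundle
#'
#' Writes beads, bonds, native contacts and crosslinks as TSV files plus the
#' native coordinates as a single-model PDB into a directory.
#'
#' @param topology a \code{ChainTopology}.
#' @param dir output directory (created if absent).
#' @param meta named list included in the header comment of each table.
#' @return the directory, invisibly.
#' @export
writeTopologyTSV <- function(topology, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(list(nResidues = topology@nResidues), meta)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    .writeHeader(f, meta)
    .appendTable(df, f)
  }
  wr(topology@beads, "beads.tsv")
  wr(rbind(cbind(topology@backboneBonds, kind = "backbone"),
           if (nrow(topology@sideBonds) > 0)
             cbind(topology@sideBonds, kind = "side")), "bonds.tsv")
  wr(topology@nativeContacts, "contacts.tsv")
  wr(data.frame(resi = topology@crosslinks[, 1],
                resj = topology@crosslinks[, 2]), "crosslinks.tsv")
  wr(topology@elements, "elements.tsv")
  writeStructurePDB(topology, file.path(dir, "native.pdb"))
  invisible(dir)
}

#' Read a topology TSV bundle
#'
#' @param dir directory written by \code{\link{writeTopologyTSV}}.
#' @return a \code{ChainTopology}.
#' @export
readTopologyTSV <- function(dir) {
  rd <- function(name) read.table(file.path(dir, name), sep = "\t",
                                  header = TRUE, comment.char = "#")
  beads <- rd("beads.tsv")
  bonds <- rd("bonds.tsv")
  contacts <- tryCatch(rd("contacts.tsv"), error = function(e)
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
               element = character(0)))
  xl <- tryCatch(rd("crosslinks.tsv"), error = function(e)
    data.frame(resi = integer(0), resj = integer(0)))
  elements <- rd("elements.tsv")
  pdbTop <- loadStructure(file.path(dir, "native.pdb"))
  n <- max(beads$residue) + 1L
  new("ChainTopology", nResidues = n, beads = beads,
      backboneBonds = bonds[bonds$kind == "backbone", c("i", "j", "b0")],
      sideBonds = bonds[bonds$kind == "side", c("i", "j", "b0")],
      nativeContacts = contacts,
      cysteines = sort(unique(as.integer(
        beads$residue[beads$resname %in% c("CYS", "CYX")]))),
      crosslinks = matrix(as.integer(as.matrix(xl)), ncol = 2),
      anchors = c(1L, n - 2L),
      nativeCoords = pdbTop@nativeCoords, cbeta = pdbTop@cbeta,
      elements = elements)
}

#' Write a structure as a single-model PDB file
#'
#' Backbone beads become CA atoms and side-centers CB atoms (so that a
#' round-trip through \code{\link{loadStructure}} recovers both centers and
#' the C-beta proxy used by the bond criterion).
#'
#' @param topology a \code{ChainTopology}.
#' @param file output path.
#' @param coords coordinates to write; default native.
#' @return the path, invisibly.
#' @export
writeStructurePDB <- function(topology, file,
                              coords = nativeCoords(topology)) {
  beads <- topology@beads
  ord <- order(beads$residue, beads$kind != "bb")
  b <- beads[ord, ]
  xyz <- as.numeric(t(coords[b$bead + 1, , drop = FALSE]))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = b$residue + 1L,
                   resid = b$resname,
                   elety = ifelse(b$kind == "bb", "CA", "CB"),
                   chain = rep("A", nrow(b)),
                   o = rep(1, nrow(b)), b = rep(0, nrow(b)))
  invisible(file)
}

#' Write a trajectory in XYZ format
#'
#' Multi-frame plain-text XYZ; one comment line per frame carries step,
#' extension and force.
#'
#' @param trajectory an \code{SMDTrajectory} with coordinates kept.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryXYZ <- function(trajectory, file) {
  if (length(trajectory@coords) == 0)
    stop("trajectory was run with keepCoords = FALSE")
  nf <- dim(trajectory@coords)[3]
  nb <- dim(trajectory@coords)[2]
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(nb), con)
    writeLines(sprintf("step=%d extension=%.3f force_pN=%.3f",
                       trajectory@log$step[f],
                       trajectory@log$extension_A[f],
                       trajectory@log$force_pN[f]), con)
    x <- t(trajectory@coords[, , f])
    writeLines(sprintf("C %.4f %.4f %.4f", x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(file)
}

#' Write the force/extension/bond-state log as TSV
#'
#' One row per saved frame: step, time, extension, force, then one distance
#' and debounced bond flag per monitored cysteine pair.
#'
#' @param trajectory an \code{SMDTrajectory}.
#' @param file output path.
#' @param meta named list for the header comment.
#' @return the path, invisibly.
#' @export
writeForceLogTSV <- function(trajectory, file, meta = list()) {
  log <- trajectory@log
  if (nrow(trajectory@pairs) > 0) {
    dn <- sprintf("d_%d_%d", trajectory@pairs$resi, trajectory@pairs$resj)
    bn <- sprintf("bonded_%d_%d", trajectory@pairs$resi, trajectory@pairs$resj)
    pd <- as.data.frame(trajectory@pairDist)
    names(pd) <- dn
    bd <- as.data.frame(trajectory@bonded)
    names(bd) <- bn
    log <- cbind(log, pd, bd)
  }
  .writeHeader(file, c(list(mode = trajectory@mode, seed = trajectory@seed),
                       meta))
  .appendTable(log, file)
  invisible(file)
}
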
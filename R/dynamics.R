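# Langevin dynamics: low-level integrator access, steered pulling runs and
# equilibrium runs with bond bookkeeping.

# debounced bond states: a state flips only after 2 consecutive saved frames
# on the other side of the cutoff
.debounce <- function(dist, cutoff = 5.5, hysteresis = 2L) {
  nf <- length(dist)
  below <- dist < cutoff
  if (nf == 0) return(logical(0))
  state <- logical(nf)
  state[1] <- below[1]
  run <- 1L
  for (t in 2:max(nf, 2)) {
    if (t > nf) break
    if (below[t] == below[t - 1]) run <- run + 1L else run <- 1L
    if (below[t] != state[t - 1] && run >= hysteresis)
      state[t] <- below[t]
    else state[t] <- state[t - 1]
  }
  state
}

.bondEvents <- function(bonded, pairs, log) {
  out <- data.frame(resi = integer(0), resj = integer(0),
                    kind = character(0), step = numeric(0),
                    extension_A = numeric(0))
  if (nrow(bonded) < 2) return(out)
  for (q in seq_len(ncol(bonded))) {
    ch <- which(diff(bonded[, q]) != 0) + 1L
    for (t in ch) {
      out <- rbind(out, data.frame(
        resi = pairs$resi[q] + 1L, resj = pairs$resj[q] + 1L,
        kind = if (bonded[t, q]) "form" else "break",
        step = log$step[t], extension_A = log$extension_A[t]))
    }
  }
  out[order(out$step), , drop = FALSE]
}

.assembleTrajectory <- function(res, pairs, mode, seed, cutoff = 5.5,
                                keepCoords = TRUE) {
  logM <- res$log
  log <- data.frame(frame = seq_len(nrow(logM)), step = logM[, 1],
                    time_fs = logM[, 2], extension_A = logM[, 3],
                    force_pN = forceToPN(logM[, 4]), epot = logM[, 5],
                    ekin = logM[, 6])
  pd <- res$pairDist
  bonded <- if (ncol(pd) > 0)
    vapply(seq_len(ncol(pd)), function(q) .debounce(pd[, q], cutoff),
           logical(nrow(pd)))
  else matrix(FALSE, nrow(pd), 0)
  if (is.vector(bonded)) bonded <- matrix(bonded, ncol = max(ncol(pd), 0))
  events <- .bondEvents(bonded, pairs, log)
  coords <- if (keepCoords && !is.null(res$coords)) res$coords
            else array(numeric(0), dim = c(3, 0, 0))
  new("SMDTrajectory", log = log,
      pairs = data.frame(resi = pairs$resi + 1L, resj = pairs$resj + 1L,
                         native = pairs$native),
      pairDist = pd, bonded = bonded, events = events, coords = coords,
      mode = mode, seed = as.integer(seed))
}

#' Run a constant-velocity steered simulation
#'
#' Prepares the system (energy minimization, then seeded thermalization at
#' the protocol temperature), tethers one anchor to its native position and
#' the other to a point moving at constant speed along the initial
#' anchor-anchor axis, and integrates BAOAB Langevin dynamics.  Frames are
#' saved at the protocol interval with the spring force (in pN), the
#' extension (current anchor separation minus the native separation) and all
#' monitored cysteine pair distances; bond events are detected with the
#' 5.5 A criterion and a 2-frame hysteresis.
#'
#' @param topology a \code{ChainTopology}.
#' @param go \code{GoParams}.
#' @param redox a \code{RedoxModel}.
#' @param protocol an \code{SMDProtocol}.
#' @param keepCoords keep saved coordinates (needed for contact-fraction and
#'   representative-structure analysis).
#' @return an \code{SMDTrajectory}.
#' @export
runSMD <- function(topology, go = GoParams(), redox = RedoxModel("dynamic"),
                   protocol = SMDProtocol(), keepCoords = TRUE) {
  validObject(protocol)
  anc <- if (length(protocol@anchors) == 2) protocol@anchors
         else topology@anchors
  if (any(anc < 0 | anc >= topology@nResidues))
    stop("protocol anchors outside the chain")
  top <- topology
  top@anchors <- as.integer(anc)

  sys <- .buildSystem(top, go, redox)
  minres <- engineMinimize(sys, nativeCoords(top),
                           maxSteps = protocol@minimizeSteps, fTol = 1e-4)
  x0 <- minres$coords

  a <- anc[1] + 1L; b <- anc[2] + 1L
  axis <- x0[b, ] - x0[a, ]
  nativeDist <- sqrt(sum(axis^2))
  axis <- axis / nativeDist
  sys$nativeDist <- nativeDist
  k <- protocol@springK
  sys$tethers <- rbind(c(anc[1], x0[a, ], k))
  gamma <- protocol@frictionBase * protocol@frictionScale
  pairs <- .monitorPairs(top, redox@mode)
  scMap <- .scBeadMap(top)
  logPairs <- if (nrow(pairs) > 0)
    cbind(scMap[pairs$resi + 1L], scMap[pairs$resj + 1L])
  else matrix(integer(0), 0, 2)
  storage.mode(logPairs) <- "integer"

  # thermalization with both anchors held
  sysT <- sys
  sysT$tethers <- rbind(sys$tethers, c(anc[2], x0[b, ], k))
  th <- engineRun(sysT, x0, NULL, dt = protocol@dt,
                  nSteps = protocol@thermalizeSteps,
                  saveEvery = max(protocol@thermalizeSteps, 1L),
                  temperature = protocol@temperature, gamma = gamma,
                  seed = as.numeric(protocol@seed) * 1000003 + 1, saveCoords = FALSE,
                  logPairs = matrix(integer(0), 0, 2))

  sysP <- sys
  sysP$moving <- list(bead = anc[2], p0 = x0[b, ], dir = axis,
                      speed = protocol@speed / .mtuFs, k = k)
  res <- engineRun(sysP, th$finalCoords, th$finalVel, dt = protocol@dt,
                   nSteps = protocol@nSteps, saveEvery = protocol@saveEvery,
                   temperature = protocol@temperature, gamma = gamma,
                   seed = as.numeric(protocol@seed) * 1000003 + 2, saveCoords = keepCoords,
                   logPairs = logPairs)
  .assembleTrajectory(res, pairs, redox@mode, protocol@seed,
                      keepCoords = keepCoords)
}

#' Run an equilibrium (no pulling) simulation
#'
#' As \code{\link{runSMD}} with zero pulling speed and no anchor tethers:
#' the chain evolves freely under the thermostat.  Used for stability
#' baselines (RMSD, radius of gyration, RMSF).
#'
#' @inheritParams runSMD
#' @param minimize relax the starting structure first.
#' @return an \code{SMDTrajectory} (extension is reported relative to the
#'   native anchor separation; the spring force is zero).
#' @export
runEquilibrium <- function(topology, go = GoParams(),
                           redox = RedoxModel("static"),
                           protocol = SMDProtocol(speed = 0),
                           keepCoords = TRUE, minimize = TRUE) {
  top <- topology
  sys <- .buildSystem(top, go, redox)
  x0 <- nativeCoords(top)
  if (minimize)
    x0 <- engineMinimize(sys, x0, maxSteps = protocol@minimizeSteps,
                         fTol = 1e-4)$coords
  gamma <- protocol@frictionBase * protocol@frictionScale
  pairs <- .monitorPairs(top, redox@mode)
  scMap <- .scBeadMap(top)
  logPairs <- if (nrow(pairs) > 0)
    cbind(scMap[pairs$resi + 1L], scMap[pairs$resj + 1L])
  else matrix(integer(0), 0, 2)
  storage.mode(logPairs) <- "integer"
  res <- engineRun(sys, x0, NULL, dt = protocol@dt,
                   nSteps = protocol@nSteps, saveEvery = protocol@saveEvery,
                   temperature = protocol@temperature, gamma = gamma,
                   seed = as.numeric(protocol@seed) * 1000003 + 2, saveCoords = keepCoords,
                   logPairs = logPairs)
  .assembleTrajectory(res, pairs, redox@mode, protocol@seed,
                      keepCoords = keepCoords)
}

#' Low-level Langevin integrator access
#'
#' Integrate an arbitrary bead system (harmonic bonds, positional tethers,
#' optionally a set of beads interacting through the disulfide double-well
#' with triplet repulsion, and flat-bottom restrained pairs) with the BAOAB
#' scheme.  With \code{gammaFs = 0} the thermostat is off and the scheme
#' reduces to velocity Verlet.  All bead indices at this interface are
#' 1-based.
#'
#' @param coords starting coordinates (n x 3), A.
#' @param bonds data.frame/matrix with columns i, j, b0, k (energy
#'   0.5 k (r - b0)^2).
#' @param tethers matrix with columns bead, x, y, z, k.
#' @param dynBeads bead indices treated as cysteine side-centers: the
#'   double-well acts on every pair and the triplet repulsion on every
#'   triple.
#' @param dynParams,tripletParams,restraintParams parameter sets.
#' @param restPairs two-column matrix of flat-bottom restrained pairs.
#' @param massAmu bead mass in amu.
#' @param dt time step, fs.
#' @param nSteps step count.
#' @param saveEvery save interval, steps.
#' @param temperature thermostat temperature, K.
#' @param gammaFs friction, fs^-1.
#' @param seed integer seed.
#' @param velocities optional starting velocities (n x 3, A/fs); default
#'   Maxwell-Boltzmann at \code{temperature}.
#' @param saveCoords keep per-frame coordinates.
#' @param logPairs two-column matrix of bead pairs whose distances are
#'   recorded per frame.
#' @return list with \code{log} (data.frame: step, time_fs, epot, ekin),
#'   \code{pairDist}, \code{coords} (3 x n x frames array if saved),
#'   \code{finalCoords}, \code{finalVel}.
#' @export
simulateLangevin <- function(coords, bonds = NULL, tethers = NULL,
                             dynBeads = NULL,
                             dynParams = DynamicSSParams(),
                             tripletParams = TripletParams(),
                             restraintParams = RestraintParams(),
                             restPairs = NULL, massAmu = .beadMassAmu,
                             dt = 0.489, nSteps = 1000L, saveEvery = 10L,
                             temperature = 300, gammaFs = 5e-5, seed = 1L,
                             velocities = NULL, saveCoords = FALSE,
                             logPairs = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  toM <- function(x, ncol_) {
    if (is.null(x)) return(matrix(0, 0, ncol_))
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
  bonds <- toM(bonds, 4); if (nrow(bonds) > 0) bonds[, 1:2] <- bonds[, 1:2] - 1
  tethers <- toM(tethers, 5)
  if (nrow(tethers) > 0) tethers[, 1] <- tethers[, 1] - 1
  restPairs <- toM(restPairs, 2)
  if (nrow(restPairs) > 0) restPairs <- restPairs - 1
  dynBeads <- if (is.null(dynBeads)) integer(0) else as.integer(dynBeads) - 1L
  ssPairs <- if (length(dynBeads) >= 2) t(combn(dynBeads, 2)) else matrix(0L, 0, 2)
  mode <- if (length(dynBeads) >= 2) 1L else if (nrow(restPairs) > 0) 3L else 0L
  lp <- if (is.null(logPairs)) matrix(integer(0), 0, 2)
        else { m <- as.matrix(logPairs) - 1L; storage.mode(m) <- "integer"; m }
  sys <- list(mass = rep(massAmu * .massUnit, n), bonds = bonds,
              contacts = matrix(0, 0, 4), evPairs = matrix(0, 0, 4),
              dihedrals = matrix(0, 0, 6), ssMode = mode, ssPairs = ssPairs,
              cysBeads = dynBeads, restPairs = restPairs,
              dynPar = .dynParVector(dynParams),
              tripletPar = c(tripletParams@a, tripletParams@b,
                             tripletParams@c, tripletParams@d),
              restPar = c(restraintParams@k, restraintParams@r1,
                          restraintParams@r2, restraintParams@r3),
              tethers = tethers, moving = NULL,
              anchorA = 0L, anchorB = 0L, nativeDist = 0)
  res <- engineRun(sys, coords, velocities, dt = dt, nSteps = as.integer(nSteps),
                   saveEvery = as.integer(saveEvery),
                   temperature = temperature, gamma = gammaFs,
                   seed = seed, saveCoords = saveCoords, logPairs = lp)
  log <- data.frame(step = res$log[, 1], time_fs = res$log[, 2],
                    epot = res$log[, 5], ekin = res$log[, 6])
  list(log = log, pairDist = res$pairDist,
       coords = if (saveCoords) res$coords else NULL,
       finalCoords = res$finalCoords, finalVel = res$finalVel)
}
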
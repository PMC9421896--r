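# Shared fixtures, built once per test run and cached.  All generated in
# code from fixed seeds; simulation ensembles are scaled to desk size.

.fixtureCache <- new.env(parent = emptyenv())

withCache <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

fold40Spec <- function(seed = 5L) {
  ToyFoldSpec(40, blocks = data.frame(
    type = c("loop", "helix", "loop", "sheet", "loop", "sheet", "loop"),
    length = c(2, 10, 4, 8, 4, 10, 2)),
    crosslinks = rbind(c(8L, 30L)), seed = seed)
}

fold40 <- function() withCache("fold40", generateToyFold(fold40Spec()))

mimic <- function() withCache("mimic", generateToyFold(rnaseMimicSpec()))

# steps so that the moving tether travels `disp` Angstrom
stepsForDisplacement <- function(disp, speed, dt = 0.489) {
  as.integer(ceiling(disp / (speed / 4.89 * dt)))
}

nativeAnchorDist <- function(top) {
  x <- nativeCoords(top)
  sqrt(sum((x[top@anchors[2] + 1, ] - x[top@anchors[1] + 1, ])^2))
}

# RNase-mimic pulling ensemble: 8 seeds x {none, weak, strong, static};
# pulled at 0.02 A/MTU to near-full extension
redoxEnsemble <- function() withCache("redoxEnsemble", {
  top <- mimic()
  # pull past the crosslink-free contour so every bond is forced to rupture
  disp <- maxExtensionBound(top, matrix(integer(0), ncol = 2)) -
    nativeAnchorDist(top) + 60
  nSteps <- stepsForDisplacement(disp, 0.02)
  conds <- list(none = RedoxModel("none"),
                weak = RedoxModel("dynamic",
                                  dynamic = DynamicSSParams(dBond = 5.5)),
                strong = RedoxModel("dynamic",
                                    dynamic = DynamicSSParams(dBond = 11.0)))
  out <- lapply(conds, function(redox)
    lapply(1:8, function(s)
      runSMD(top, redox = redox,
             protocol = SMDProtocol(speed = 0.02, nSteps = nSteps,
                                    seed = s), keepCoords = FALSE)))
  # static arm: pulled to just past its (much shorter) contour bound
  dispS <- maxExtensionBound(top) - nativeAnchorDist(top) + 10
  out$static <- lapply(1:8, function(s)
    runSMD(top, redox = RedoxModel("static"),
           protocol = SMDProtocol(speed = 0.02,
                                  nSteps = stepsForDisplacement(dispS, 0.02),
                                  seed = s), keepCoords = FALSE))
  out
})

# static-mode run pulled to just past the contour bound
staticCeilingRun <- function() withCache("staticCeilingRun", {
  top <- fold40()
  bound <- maxExtensionBound(top)
  disp <- bound - nativeAnchorDist(top) + 15
  runSMD(top, redox = RedoxModel("static"),
         protocol = SMDProtocol(speed = 0.02,
                                nSteps = stepsForDisplacement(disp, 0.02),
                                seed = 3L), keepCoords = FALSE)
})

# mean maximum force and ensemble first-peak position per pulling speed
speedScan <- function() withCache("speedScan", {
  top <- fold40()
  disp <- 0.85 * (maxExtensionBound(top, matrix(integer(0), ncol = 2)) -
                  nativeAnchorDist(top))
  lapply(c(0.005, 0.01, 0.02), function(sp) {
    trs <- lapply(1:8, function(s)
      runSMD(top, redox = RedoxModel("dynamic"),
             protocol = SMDProtocol(speed = sp,
                                    nSteps = stepsForDisplacement(disp, sp),
                                    seed = s), keepCoords = FALSE))
    prof <- binForceExtension(trs)
    pks <- detectPeaks(prof)
    mx <- pks[pks$kind == "maximum", , drop = FALSE]
    list(speed = sp,
         meanMaxForce = mean(vapply(trs, function(t) max(t@log$force_pN),
                                    numeric(1))),
         firstPeak = if (nrow(mx) > 0) mx$extension_A[1] else NA,
         profile = prof)
  })
})

# single tethered bonded pair pulled to rupture; force read at the final
# break event
rupturePull <- function(dBond, seed) {
  top <- withCache("pairFold", generateToyFold(
    ToyFoldSpec(8, blocks = data.frame(type = "loop", length = 8),
                crosslinks = rbind(c(1L, 6L)), seed = 2L)))
  tr <- runSMD(top,
               redox = RedoxModel("dynamic",
                                  dynamic = DynamicSSParams(dBond = dBond)),
               protocol = SMDProtocol(speed = 0.01, nSteps = 60000L,
                                      seed = seed), keepCoords = FALSE)
  ev <- bondEvents(tr)
  brk <- ev[ev$kind == "break", , drop = FALSE]
  if (nrow(brk) == 0) return(NA_real_)
  max(tr@log$force_pN[tr@log$step <= max(brk$step)])
}

ruptureForces <- function() withCache("ruptureForces", list(
  weak = vapply(1:8, function(s) rupturePull(5.5, s), numeric(1)),
  strong = vapply(1:8, function(s) rupturePull(11.0, s), numeric(1))))

# final break extension of the last native crosslink, per trajectory
lastNativeBreak <- function(tr) {
  ev <- bondEvents(tr)
  nat <- tr@pairs[tr@pairs$native, , drop = FALSE]
  natLab <- sprintf("%d-%d", nat$resi, nat$resj)
  brk <- ev[ev$kind == "break" &
            sprintf("%d-%d", ev$resi, ev$resj) %in% natLab, , drop = FALSE]
  if (nrow(brk) == 0) return(NA_real_)
  max(brk$extension_A)
}

# per-trajectory distance from each native pair's final break to the nearest
# force maximum (50 pN prominence on the 1 A binned profile)
breakToPeakDistances <- function(trajectories) {
  out <- numeric(0)
  for (tr in trajectories) {
    ev <- bondEvents(tr)
    natp <- tr@pairs[tr@pairs$native, , drop = FALSE]
    pk <- detectPeaks(binForceExtension(tr), prominence = 50)
    mx <- pk$extension_A[pk$kind == "maximum"]
    if (length(mx) == 0) next
    for (q in seq_len(nrow(natp))) {
      b <- ev[ev$kind == "break" & ev$resi == natp$resi[q] &
              ev$resj == natp$resj[q], , drop = FALSE]
      if (nrow(b) == 0) next
      out <- c(out, min(abs(mx - max(b$extension_A))))
    }
  }
  out
}

# extension at which a pair's ensemble bond fraction first drops below 0.5
fractionDropExtension <- function(bf, label) {
  sub <- bf[bf$label == label, , drop = FALSE]
  sub <- sub[order(sub$mid), ]
  below <- which(sub$fraction < 0.5)
  if (length(below) == 0) return(NA_real_)
  sub$mid[below[1]]
}

# minimal hand-built trajectory for analysis-layer tests
makeFakeTraj <- function(extension, force, mode = "dynamic",
                         pairs = data.frame(resi = integer(0),
                                            resj = integer(0),
                                            native = logical(0)),
                         pairDist = matrix(numeric(0), length(extension), 0),
                         coords = array(numeric(0), dim = c(3, 0, 0)),
                         events = NULL, step = NULL) {
  nf <- length(extension)
  if (is.null(step)) step <- seq_len(nf) * 200
  log <- data.frame(frame = seq_len(nf), step = step,
                    time_fs = step * 0.489, extension_A = extension,
                    force_pN = force, epot = 0, ekin = 0)
  bonded <- pairDist < 5.5
  if (is.null(events))
    events <- data.frame(resi = integer(0), resj = integer(0),
                         kind = character(0), step = numeric(0),
                         extension_A = numeric(0))
  new("SMDTrajectory", log = log, pairs = pairs, pairDist = pairDist,
      bonded = bonded, events = events, coords = coords, mode = mode,
      seed = 1L)
}
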
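# Top-level driver: YAML run configuration, the mode x speed x seed grid,
# and the per-condition analysis bundle.

#' Default run configuration
#'
#' A fully serializable description of a study: the toy-fold source, the
#' potential parameters, the protocol grid (modes x speeds x seeds) and the
#' analysis options.  All randomness is traceable to \code{masterSeed}.
#'
#' @param nResidues chain length of the toy fold (ignored when
#'   \code{rnaseMimic} is TRUE).
#' @param rnaseMimic use the RNase-A-like 124-residue mimic.
#' @param modes redox modes to run.
#' @param speeds pulling speeds, A/MTU.
#' @param nSeeds trajectories per condition.
#' @param nSteps pulling steps (NULL: chosen from the extension bound).
#' @param masterSeed master seed.
#' @param dBondWeak,dBondStrong bonded-well depths for the weakly and highly
#'   oxidizing dynamic conditions.
#' @return a named list.
#' @export
defaultRunConfig <- function(nResidues = 40, rnaseMimic = FALSE,
                             modes = c("none", "dynamic-weak",
                                       "dynamic-strong", "static"),
                             speeds = 0.02, nSeeds = 2, nSteps = NULL,
                             masterSeed = 1, dBondWeak = 5.5,
                             dBondStrong = 11.0) {
  list(topology = list(rnaseMimic = rnaseMimic, nResidues = nResidues,
                       seed = masterSeed),
       go = list(epsContact = 1.0, bondK = 100, dihedralK = 0.3),
       redox = list(dBondWeak = dBondWeak, dBondStrong = dBondStrong),
       protocol = list(speeds = speeds, springK = 1.0, temperature = 300,
                       frictionScale = 0.01, dt = 0.489, saveEvery = 200,
                       nSteps = nSteps),
       grid = list(modes = modes, nSeeds = nSeeds),
       analysis = list(binWidth = 1.0, cutoff = 5.5, peakWindow = 5),
       masterSeed = masterSeed)
}

#' Write / read a run configuration
#'
#' YAML round-trips are identity on the configuration list.
#'
#' @param config a configuration list.
#' @param file path.
#' @return \code{readRunConfig} returns the configuration list.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) yaml::read_yaml(file)

.configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

.redoxForMode <- function(mode, cfg) {
  switch(mode,
    "none" = RedoxModel("none"),
    "dynamic-weak" = RedoxModel("dynamic",
      dynamic = DynamicSSParams(dBond = cfg$redox$dBondWeak)),
    "dynamic-strong" = RedoxModel("dynamic",
      dynamic = DynamicSSParams(dBond = cfg$redox$dBondStrong)),
    "static" = RedoxModel("static"),
    "restraint" = RedoxModel("restraint"),
    stop("unknown mode: ", mode))
}

.internalMode <- function(mode) sub("-.*", "", mode)

#' Run the full pipeline: generate, simulate, analyse, report
#'
#' Generates (or mimics) the toy fold, runs the protocol grid, and writes
#' per-condition force-extension profiles, bond-fraction curves, peak and
#' event tables, breaking orders, plus a cross-mode summary, all as TSV
#' under \code{outDir}.  Re-running with the same configuration produces
#' byte-identical numeric outputs.  Trajectories that fail numerically are
#' excluded and counted in the summary.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}) or
#'   a YAML path.
#' @param outDir output directory.
#' @param keepCoords keep coordinates in memory for representative-structure
#'   analysis.
#' @return invisibly, a list with the topology, per-condition results and
#'   the summary data.frame.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile(),
                        keepCoords = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  meta <- list(config_hash = hash, master_seed = config$masterSeed)

  spec <- if (isTRUE(config$topology$rnaseMimic))
    rnaseMimicSpec(seed = config$topology$seed)
  else
    ToyFoldSpec(config$topology$nResidues,
                blocks = data.frame(
                  type = c("loop", "helix", "loop", "sheet", "loop", "sheet",
                           "loop"),
                  length = .tileBlocks(config$topology$nResidues)),
                crosslinks = .defaultCrosslinks(config$topology$nResidues),
                seed = config$topology$seed)
  go <- GoParams(epsContact = config$go$epsContact, bondK = config$go$bondK,
                 dihedralK = config$go$dihedralK)
  top <- generateToyFold(spec, go = go)
  writeTopologyTSV(top, file.path(outDir, "topology"), meta = meta)

  bound <- maxExtensionBound(top, intact = matrix(integer(0), ncol = 2))
  nativeAnchorDist <- sqrt(sum((nativeCoords(top)[top@anchors[2] + 1, ] -
                                nativeCoords(top)[top@anchors[1] + 1, ])^2))
  results <- list()
  summary <- NULL
  failures <- 0L
  for (mode in config$grid$modes) {
    redox <- .redoxForMode(mode, config)
    for (speed in config$protocol$speeds) {
      nSteps <- config$protocol$nSteps
      if (is.null(nSteps)) {
        pullLen <- 0.95 * bound - nativeAnchorDist + 20
        nSteps <- ceiling(pullLen / (speed / .mtuFs * config$protocol$dt))
      }
      trajs <- list()
      for (s in seq_len(config$grid$nSeeds)) {
        seed <- config$masterSeed * 1000 + s
        pr <- SMDProtocol(speed = speed, springK = config$protocol$springK,
                          temperature = config$protocol$temperature,
                          frictionScale = config$protocol$frictionScale,
                          dt = config$protocol$dt,
                          nSteps = as.integer(nSteps),
                          saveEvery = as.integer(config$protocol$saveEvery),
                          seed = as.integer(seed))
        tr <- tryCatch(runSMD(top, go, redox, pr, keepCoords = keepCoords),
                       error = function(e) {
                         warning(sprintf("trajectory failed (%s, seed %d): %s",
                                         mode, seed, conditionMessage(e)))
                         NULL
                       })
        if (is.null(tr)) { failures <- failures + 1L; next }
        trajs[[length(trajs) + 1]] <- tr
      }
      if (length(trajs) == 0) next
      cond <- sprintf("%s_v%g", mode, speed)
      prof <- binForceExtension(trajs, config$analysis$binWidth)
      peaks <- detectPeaks(prof, window = config$analysis$peakWindow)
      events <- do.call(rbind, lapply(seq_along(trajs), function(q)
        if (nrow(trajs[[q]]@events) > 0)
          cbind(trajectory = q, trajs[[q]]@events)))
      ord <- breakingOrder(trajs)
      bf <- if (nrow(trajs[[1]]@pairs) > 0)
        bondFractionVsExtension(trajs, cutoff = config$analysis$cutoff,
                                binWidth = config$analysis$binWidth)
      f <- function(df, name) {
        path <- file.path(outDir, sprintf("%s_%s.tsv", cond, name))
        .writeHeader(path, meta)
        .appendTable(df, path)
      }
      f(prof@profile, "profile")
      if (nrow(peaks) > 0) f(peaks, "peaks")
      if (!is.null(events)) f(events, "events")
      f(ord, "breaking_order")
      if (!is.null(bf)) f(bf, "bond_fraction")
      lastBreak <- vapply(trajs, function(t) {
        br <- t@events[t@events$kind == "break", , drop = FALSE]
        nat <- t@pairs$native
        natLab <- sprintf("%d-%d", t@pairs$resi[nat], t@pairs$resj[nat])
        brNat <- br[sprintf("%d-%d", br$resi, br$resj) %in% natLab, ,
                    drop = FALSE]
        if (nrow(brNat) == 0) NA_real_ else max(brNat$extension_A)
      }, numeric(1))
      summary <- rbind(summary, data.frame(
        mode = mode, speed = speed, nTrajectories = length(trajs),
        maxMeanForce_pN = max(prof@profile$mean_force_pN),
        peakExtension_A = if (nrow(peaks) > 0)
          peaks$extension_A[which.max(peaks$force_pN)] else NA,
        lastNativeBreak_A = stats::median(lastBreak, na.rm = TRUE),
        nUnbrokenTraj = sum(is.na(lastBreak))))
      results[[cond]] <- list(trajectories = trajs, profile = prof,
                              peaks = peaks, order = ord)
    }
  }
  if (!is.null(summary)) {
    path <- file.path(outDir, "summary.tsv")
    .writeHeader(path, c(meta, list(failed_trajectories = failures)))
    .appendTable(summary, path)
  }
  invisible(list(topology = top, results = results, summary = summary,
                 failures = failures, outDir = outDir))
}

# simple block tiling for generic toy folds: two strand/helix columns with
# connecting loops
.tileBlocks <- function(n) {
  body <- n - 4
  a <- body %/% 3
  b <- body %/% 3
  c <- body - a - b - 2
  c(2, a, 1, b, 1, c, 2)
}

.defaultCrosslinks <- function(n) {
  # one crosslink between the two inner secondary blocks
  lens <- .tileBlocks(n)
  start <- cumsum(c(0, lens))
  i <- start[2] + lens[2] %/% 2
  j <- start[4] + lens[4] %/% 2
  matrix(as.integer(c(i, j)), ncol = 2)
}
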
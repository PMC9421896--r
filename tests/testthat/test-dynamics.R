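# Integrator correctness, pulling protocol behaviour, bond bookkeeping and
# the mode-dependent contracts.

test_that("with the thermostat off the integrator conserves energy", {
  x <- rbind(c(0, 0, 0), c(4.3, 0, 0))
  r <- simulateLangevin(x, bonds = cbind(1, 2, 3.8, 100), dt = 0.489,
                        nSteps = 10000, saveEvery = 10, temperature = 0,
                        gammaFs = 0, seed = 1)
  E <- r$log$epot + r$log$ekin
  expect_lt((max(E) - min(E)) / abs(E[1]), 0.001)  # < 0.1 % drift
})

test_that("a tethered bead equilibrates to the equipartition variance", {
  r <- simulateLangevin(matrix(0, 1, 3), tethers = cbind(1, 0, 0, 0, 1.0),
                        dt = 0.489, nSteps = 8e5, saveEvery = 20,
                        temperature = 300, gammaFs = 5e-3, seed = 2,
                        saveCoords = TRUE)
  xs <- r$coords[1, 1, ]
  kT <- unitSystem()$kB_kcal_mol_K * 300
  # per-block second moment about the global mean (block means would bias
  # the variance low); block SE handles autocorrelation
  nb <- 50
  mu <- mean(xs)
  blocks <- split(xs, rep(seq_len(nb), each = ceiling(length(xs) / nb))[
    seq_along(xs)])
  vs <- vapply(blocks, function(b) mean((b - mu)^2), numeric(1))
  se <- stats::sd(vs) / sqrt(nb)
  expect_lt(abs(mean(vs) - kT), 3 * se)
})

test_that("identical protocol and seed give identical trajectories", {
  top <- fold40()
  pr <- SMDProtocol(speed = 0.02, nSteps = 5000L, seed = 42L)
  a <- runSMD(top, redox = RedoxModel("dynamic"), protocol = pr)
  b <- runSMD(top, redox = RedoxModel("dynamic"), protocol = pr)
  expect_identical(a@log, b@log)
  expect_identical(a@coords, b@coords)
  c <- runSMD(top, redox = RedoxModel("dynamic"),
              protocol = SMDProtocol(speed = 0.02, nSteps = 5000L, seed = 43L))
  expect_false(identical(a@log$force_pN, c@log$force_pN))
})

test_that("the equilibrium occupancy of the double well is Boltzmann", {
  # shallow wells so both minima are thermally accessible on the run length;
  # a weak harmonic link confines the pair without biasing either well
  dp <- DynamicSSParams(dBond = 1.5, dContact = 0.75)
  kT <- unitSystem()$kB_kcal_mol_K * 300
  r <- simulateLangevin(rbind(c(0, 0, 0), c(4, 0, 0)),
                        bonds = cbind(1, 2, 6.0, 0.5), dynBeads = c(1, 2),
                        dynParams = dp, dt = 0.489, nSteps = 2e7,
                        saveEvery = 20, temperature = 300, gammaFs = 5e-3,
                        seed = 11, logPairs = cbind(1, 2))
  d <- r$pairDist[, 1]                      # 1e6 saved samples
  edges <- seq(2.5, 11, by = 0.25)
  pref <- boltzmannReference(function(z)
    uDynSS(z, dp)$energy + 0.5 * 0.5 * (z - 6)^2, edges, kT)
  h <- hist(d, breaks = edges, plot = FALSE)
  pobs <- h$counts / sum(h$counts)
  nb <- 200
  blk <- split(d, rep(seq_len(nb), each = ceiling(length(d) / nb))[
    seq_along(d)])
  bp <- vapply(blk, function(v)
    hist(v, breaks = edges, plot = FALSE)$counts / length(v),
    numeric(length(edges) - 1))
  se <- apply(bp, 1, stats::sd) / sqrt(nb)
  keep <- pref > 1e-4                        # populated bins
  z <- (pobs[keep] - pref[keep]) / pmax(se[keep], 1e-12)
  expect_lt(max(abs(z)), 3)
})

test_that("without pulling the extension fluctuates about zero", {
  top <- fold40()
  tr <- runSMD(top, redox = RedoxModel("static"),
               protocol = SMDProtocol(speed = 1e-9, nSteps = 10000L,
                                      seed = 2L), keepCoords = FALSE)
  expect_lt(abs(mean(tr@log$extension_A)), 2)
  # mean |force| below the 2 kT/A thermal scale
  kT <- unitSystem()$kB_kcal_mol_K * 300
  expect_lt(mean(abs(tr@log$force_pN)), forceToPN(2 * kT))
})

test_that("static mode never produces bond events", {
  tr <- staticCeilingRun()
  expect_identical(nrow(bondEvents(tr)), 0L)
  expect_true(all(tr@bonded))
})

test_that("static bonds cap the extension at the contour bound", {
  top <- fold40()
  tr <- staticCeilingRun()
  bound <- maxExtensionBound(top)
  ceiling_ <- bound - nativeAnchorDist(top) + 5
  expect_lte(unname(quantile(tr@log$extension_A, 0.99)), ceiling_)
})

test_that("in the highly oxidizing mode every native crosslink eventually breaks", {
  ens <- redoxEnsemble()
  for (tr in ens$strong) {
    ev <- bondEvents(tr)
    nat <- tr@pairs[tr@pairs$native, ]
    for (q in seq_len(nrow(nat))) {
      hit <- ev$kind == "break" & ev$resi == nat$resi[q] &
             ev$resj == nat$resj[q]
      expect_gt(sum(hit), 0)
    }
  }
})

test_that("no cysteine is ever bonded to two partners at once", {
  ens <- redoxEnsemble()
  for (mode in c("weak", "strong")) for (tr in ens[[mode]]) {
    bonded <- tr@pairDist < 5.5            # raw per-frame criterion
    for (cys in unique(c(tr@pairs$resi, tr@pairs$resj))) {
      cols <- which(tr@pairs$resi == cys | tr@pairs$resj == cys)
      perCys <- rowSums(bonded[, cols, drop = FALSE])
      expect_lte(max(perCys), 1)
    }
  }
})

test_that("mean maximum force grows with pulling speed and peaks shift outward", {
  sc <- speedScan()
  maxF <- vapply(sc, function(s) s$meanMaxForce, numeric(1))
  expect_true(all(diff(maxF) >= 0))
  firstPeak <- vapply(sc, function(s) s$firstPeak, numeric(1))
  # the first unfolding peak moves toward longer extensions (1 A bins)
  expect_gte(firstPeak[3], firstPeak[1])
})

test_that("lowering the temperature shifts peaks like faster pulling does", {
  top <- fold40()
  disp <- 0.85 * (maxExtensionBound(top, matrix(integer(0), ncol = 2)) -
                  nativeAnchorDist(top))
  nSteps <- stepsForDisplacement(disp, 0.01)
  first <- function(temp) {
    trs <- lapply(1:8, function(s)
      runSMD(top, redox = RedoxModel("dynamic"),
             protocol = SMDProtocol(speed = 0.01, temperature = temp,
                                    nSteps = nSteps, seed = s),
             keepCoords = FALSE))
    pks <- detectPeaks(binForceExtension(trs))
    pks$extension_A[pks$kind == "maximum"][1]
  }
  # same direction as faster pulling, within the 1 A binning noise
  expect_gte(first(278), first(300) - 2)
})

test_that("a zero-length run returns only the initial frame", {
  top <- fold40()
  tr <- runEquilibrium(top, protocol = SMDProtocol(speed = 0, nSteps = 0L,
                                                   seed = 1L))
  expect_identical(nrow(tr@log), 1L)
  expect_identical(dim(tr@coords)[3], 1L)
})

test_that("the toy fold is stable in equilibrium and disulfide-free runs are no more compact", {
  top <- fold40()
  core <- top@elements$residue[grepl("^[HB]", top@elements$element)] + 1L
  eq <- function(mode, seed) runEquilibrium(
    top, redox = RedoxModel(mode),
    protocol = SMDProtocol(speed = 0, nSteps = 100000L, seed = seed,
                           saveEvery = 500L))
  ts <- eq("static", 1L)
  nat <- nativeCoords(top)[core, ]
  rms <- vapply(seq_len(dim(ts@coords)[3]), function(f)
    kabschRMSD(t(ts@coords[, core, f]), nat), numeric(1))
  expect_lt(mean(rms), 3.0)
  rgS <- mean(rgRgmaxRmsf(ts)$rg)
  rgN <- mean(rgRgmaxRmsf(eq("none", 1L))$rg)
  expect_gte(rgN, rgS - 0.5)
})

test_that("anchors outside the chain are rejected", {
  top <- fold40()
  expect_error(runSMD(top, protocol = SMDProtocol(anchors = c(1L, 99L),
                                                  nSteps = 100L)),
               "anchors outside")
})
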
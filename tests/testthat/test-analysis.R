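# Analysis layer: binning, break-force correction, fractions, peaks,
# representatives, RMSD and breaking order.

test_that("constant-force logs bin to the exact mean and SEM", {
  t1 <- makeFakeTraj(extension = seq(0.2, 9.8, by = 0.2), force = 100)
  p <- binForceExtension(t1)@profile
  expect_true(all(p$mean_force_pN == 100))
  expect_true(all(p$sem_pN == 0))
  expect_identical(sum(p$n), 49)
  # two constant-force trajectories: mean (f1+f2)/2, SEM |f1-f2|/2 for n = 2
  t2 <- makeFakeTraj(extension = seq(0.2, 9.8, by = 0.2), force = 150)
  ext <- c(0.5, 1.5)
  a <- makeFakeTraj(ext, force = 100)
  b <- makeFakeTraj(ext, force = 150)
  p2 <- binForceExtension(list(a, b))@profile
  expect_true(all(p2$mean_force_pN == 125))
  expect_true(all(abs(p2$sem_pN - 25) < 1e-12))   # sd/sqrt(2) = |d|/2
  expect_true(all(p2$n == 2))
})

test_that("binning is invariant under frame order and conserves observations", {
  set.seed(3)
  ext <- runif(500, 0, 50)
  f <- rnorm(500, 200, 30)
  a <- binForceExtension(makeFakeTraj(ext, f))
  perm <- sample(500)
  b <- binForceExtension(makeFakeTraj(ext[perm], f[perm]))
  expect_equal(a@profile, b@profile)
  expect_identical(sum(a@profile$n), 500)
  expect_error(binForceExtension(list()), "at least one")
})

test_that("empty bins are absent rather than zero", {
  p <- binForceExtension(makeFakeTraj(c(0.5, 30.5), c(10, 20)))@profile
  expect_identical(nrow(p), 2L)
  expect_false(any(p$n == 0))
})

test_that("break-force subtraction steps down once per broken restraint", {
  prs <- data.frame(resi = c(5L, 7L), resj = c(18L, 20L),
                    native = c(TRUE, TRUE))
  ext <- seq(1, 100, by = 1)
  mk <- function(events) makeFakeTraj(ext, force = 1000, mode = "restraint",
                                      pairs = prs,
                                      pairDist = matrix(4, length(ext), 2),
                                      events = events, step = ext * 100)
  # no break events: unchanged
  t0 <- mk(NULL)
  expect_identical(subtractBreakForce(t0)@log$force_pN, t0@log$force_pN)
  # one break at extension 40
  ev1 <- data.frame(resi = 5L, resj = 18L, kind = "break", step = 4000,
                    extension_A = 40)
  c1 <- subtractBreakForce(mk(ev1))@log$force_pN
  fconst <- forceToPN(8.0)
  expect_equal(unique(c1[ext < 40]), 1000)
  expect_equal(unique(c1[ext >= 40]), 1000 - fconst)
  # break + reformation + final break: only the final break counts
  ev2 <- rbind(ev1,
               data.frame(resi = 5L, resj = 18L, kind = "form", step = 5000,
                          extension_A = 50),
               data.frame(resi = 5L, resj = 18L, kind = "break", step = 6000,
                          extension_A = 60),
               data.frame(resi = 7L, resj = 20L, kind = "break", step = 8000,
                          extension_A = 80))
  c2 <- subtractBreakForce(mk(ev2))@log$force_pN
  expect_equal(unique(c2[ext < 60]), 1000)
  expect_equal(unique(c2[ext >= 60 & ext < 80]), 1000 - fconst)
  expect_equal(unique(c2[ext >= 80]), 1000 - 2 * fconst)
  # non-restraint trajectories are refused
  expect_error(subtractBreakForce(makeFakeTraj(1:3, 1, mode = "dynamic")),
               "restraint")
})

test_that("bond fractions are per-bin bonded-observation fractions", {
  prs <- data.frame(resi = 5L, resj = 18L, native = TRUE)
  ext <- rep(c(0.5, 1.5), each = 4)
  d <- c(rep(4, 4), c(4, 4, 6, 6))      # second bin half bonded
  tr <- makeFakeTraj(ext, 0, pairs = prs, pairDist = matrix(d, ncol = 1))
  bf <- bondFractionVsExtension(tr)
  expect_equal(bf$fraction, c(1.0, 0.5))
  expect_true(all(bf$fraction >= 0 & bf$fraction <= 1))
  expect_error(bondFractionVsExtension(tr, pairs = cbind(1, 2)),
               "unknown pair")
})

test_that("contact fractions are high in the native ensemble and low when extended", {
  top <- fold40()
  nb <- nrow(nativeCoords(top))
  mkCoords <- function(x) array(t(x), dim = c(3, nb, 2))
  natTr <- makeFakeTraj(c(0, 0), 0, coords = mkCoords(nativeCoords(top)))
  # elements with no contacts of their own are excluded with a warning
  expect_warning(cf <- contactFractionByElement(natTr, top), "excluded")
  expect_true(all(cf$fraction > 0.9))
  # fully extended chain: all contacts lost
  stretched <- cbind(seq_len(nb) * 3.8, 0, 0)
  extTr <- makeFakeTraj(c(400, 400), 0, coords = mkCoords(stretched))
  expect_warning(cfE <- contactFractionByElement(extTr, top), "excluded")
  expect_true(all(cfE$fraction < 0.1))
})

test_that("peak detection finds shaped pulses and ignores flat noise", {
  mkProf <- function(y) {
    ext <- seq_along(y) - 0.5
    binForceExtension(makeFakeTraj(ext, y))
  }
  # one triangular pulse
  tri <- c(rep(0, 10), seq(0, 300, length.out = 11),
           seq(300, 0, length.out = 11)[-1], rep(0, 10))
  p1 <- detectPeaks(mkProf(tri), prominence = 50)
  expect_identical(sum(p1$kind == "maximum"), 1L)
  apex <- p1$extension_A[p1$kind == "maximum"]
  expect_lt(abs(apex - 20.5), 2)
  # two separated pulses: two maxima, one interior minimum
  two <- c(tri, tri)
  p2 <- detectPeaks(mkProf(two), prominence = 50)
  expect_identical(sum(p2$kind == "maximum"), 2L)
  expect_identical(sum(p2$kind == "minimum"), 1L)
  expect_true(all(diff(match(p2$kind, c("maximum", "minimum"))) != 0))
  # pure noise below the prominence threshold
  set.seed(8)
  p3 <- detectPeaks(mkProf(rnorm(60, 0, 1)), prominence = 50)
  expect_identical(nrow(p3), 0L)
})

test_that("Kabsch RMSD is zero under rigid motion and matches the quaternion oracle", {
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3)
  expect_lt(kabschRMSD(X, X), 1e-10)
  # random proper rotation + translation
  ang <- runif(3, 0, 2 * pi)
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  R <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
  Y <- X %*% R + matrix(rep(c(3, -2, 7), each = 10), 10, 3)
  expect_lt(kabschRMSD(X, Y), 1e-8)
  for (rep in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(kabschRMSD(A, B) - quatRMSD(A, B)), 1e-6)
  }
  expect_error(kabschRMSD(X, X[1:5, ]), "mismatch")
})

test_that("after common superposition the pairwise deviations obey the triangle bound", {
  set.seed(13)
  ref <- matrix(rnorm(30), 10, 3)
  frames <- lapply(1:3, function(i) superpose(ref + matrix(rnorm(30, sd = 0.5),
                                                           10, 3), ref))
  plainRMSD <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  d12 <- plainRMSD(frames[[1]], frames[[2]])
  d23 <- plainRMSD(frames[[2]], frames[[3]])
  d13 <- plainRMSD(frames[[1]], frames[[3]])
  expect_lte(d13, d12 + d23 + 1e-6)
})

test_that("the representative minimizes the RMSD sum with lowest-id ties", {
  nb <- 10
  set.seed(14)
  A <- matrix(rnorm(3 * nb, sd = 2), nb, 3)
  C <- A + matrix(rnorm(3 * nb, sd = 2), nb, 3)
  B <- (A + C) / 2
  mk <- function(frames) {
    co <- array(unlist(lapply(frames, t)), dim = c(3, nb, length(frames)))
    makeFakeTraj(rep(10, length(frames)), 0, coords = co)
  }
  # midpoint structure B has the smallest total deviation
  r <- selectRepresentative(mk(list(A, B, C)), extension = 10)
  expect_identical(r$frame$frame, 2L)
  # singleton ensemble: that frame with sum 0
  r1 <- selectRepresentative(mk(list(A)), extension = 10)
  expect_identical(r1$frame$frame, 1L)
  expect_identical(r1$rmsdSum, 0)
  # duplicated frames tie; lowest frame id wins
  r2 <- selectRepresentative(mk(list(A, A, A)), extension = 10)
  expect_identical(r2$frame$frame, 1L)
  # empty window names the extension
  expect_error(selectRepresentative(mk(list(A)), extension = 99),
               "99")
})

test_that("representative selection equals the exhaustive oracle on real ensembles", {
  top <- fold40()
  disp <- 60
  tr <- withCache("repTraj", runSMD(
    top, redox = RedoxModel("dynamic"),
    protocol = SMDProtocol(speed = 0.02,
                           nSteps = stepsForDisplacement(disp, 0.02),
                           seed = 6L), keepCoords = TRUE))
  for (target in c(10, 25, 40)) {
    r <- selectRepresentative(tr, extension = target, window = 2.5)
    sel <- which(abs(tr@log$extension_A - target) <= 2.5)
    expect_lte(length(sel), 30)
    coordsList <- lapply(sel, function(f) t(tr@coords[, , f]))
    oracle <- exhaustiveRepresentative(coordsList)
    expect_identical(r$frame$frame, sel[oracle$index])
    expect_equal(r$rmsdSum, oracle$sums, tolerance = 1e-6)
  }
})

test_that("Rg, Rgmax and RMSF follow their definitions", {
  # two beads separated by d: Rg = Rgmax = d/2
  co <- array(0, dim = c(3, 2, 2))
  co[, 2, ] <- c(6, 0, 0)
  tr <- makeFakeTraj(c(0, 0), 0, coords = co)
  r <- rgRgmaxRmsf(tr)
  expect_equal(r$rg, c(3, 3))
  expect_equal(r$rgmax, c(3, 3))
  # static trajectory: zero fluctuation
  expect_true(all(r$rmsf < 1e-12))
  # all beads coincident: zero radius
  z <- makeFakeTraj(c(0, 0), 0, coords = array(1, dim = c(3, 4, 2)))
  expect_equal(rgRgmaxRmsf(z)$rg, c(0, 0))
  # single frame: RMSF undefined
  one <- makeFakeTraj(0, 0, coords = array(0, dim = c(3, 2, 1)))
  expect_error(rgRgmaxRmsf(one), "single frame")
})

test_that("breaking order ranks final break extensions with unbroken last", {
  prs <- data.frame(resi = c(1L, 2L, 3L), resj = c(11L, 12L, 13L),
                    native = TRUE)
  mkEv <- function(df) makeFakeTraj(seq(1, 200), 0, pairs = prs,
                                    pairDist = matrix(4, 200, 3),
                                    events = df, step = seq(1, 200) * 100)
  ev <- data.frame(resi = c(2L, 1L, 3L), resj = c(12L, 11L, 13L),
                   kind = "break", step = c(5000, 10000, 15000),
                   extension_A = c(50, 100, 150))
  ord <- breakingOrder(mkEv(ev))
  expect_identical(ord$label, c("2-12", "1-11", "3-13"))
  # reformation before the last break is ignored
  ev2 <- rbind(ev, data.frame(resi = 2L, resj = 12L,
                              kind = c("form", "break"),
                              step = c(6000, 18000),
                              extension_A = c(60, 180)))
  ord2 <- breakingOrder(mkEv(ev2))
  expect_identical(ord2$label, c("1-11", "3-13", "2-12"))
  expect_equal(ord2$meanFinalBreak_A[ord2$label == "2-12"], 180)
  # static mode: everything unbroken
  ord3 <- breakingOrder(mkEv(NULL))
  expect_true(all(is.na(ord3$medianRank)))
  expect_true(all(ord3$nBroken == 0))
})
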
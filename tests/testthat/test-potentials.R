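# Energy terms: double-well disulfide potential, triplet repulsion,
# flat-bottom restraint, structure-based background, and force-gradient
# consistency.

test_that("the double well has its bonded minimum at rBond with depth dBond", {
  u <- uDynSS(4.0)
  expect_lt(abs(u$energy - (-5.5)) / 5.5, 0.02)
  u11 <- uDynSS(4.0, DynamicSSParams(dBond = 11.0))
  expect_lt(abs(u11$energy - (-11.0)) / 11.0, 0.02)
  # smooth curve: force vanishes near both minima
  expect_lt(abs(uDynSS(4.0)$force), 0.5)
  expect_lt(abs(uDynSS(6.5)$force), 0.5)
  # barrier between the wells
  rg <- seq(4.2, 6.3, by = 0.01)
  expect_gt(max(uDynSS(rg)$energy), uDynSS(6.5)$energy)
})

test_that("the redox setting leaves the contact minimum untouched", {
  uWeak <- uDynSS(6.5, DynamicSSParams(dBond = 5.5))$energy
  uStrong <- uDynSS(6.5, DynamicSSParams(dBond = 11.0))$energy
  expect_lt(abs(uWeak - uStrong) / abs(uWeak), 0.01)
  # bonded-well depth doubles, so the formed/broken barrier grows with dBond
  barrier <- function(dB) {
    p <- DynamicSSParams(dBond = dB)
    rg <- seq(p@rBond, p@rContact, by = 0.005)
    max(uDynSS(rg, p)$energy) - uDynSS(p@rBond, p)$energy
  }
  bs <- vapply(c(5.5, 8.0, 11.0), barrier, numeric(1))
  expect_true(all(diff(bs) > 0))
  expect_lt(abs(bs[3] / bs[1] - 2), 0.15)  # effectively doubled
})

test_that("the double well decays to zero at large separation", {
  expect_lt(abs(uDynSS(50)$energy), 1e-3)
  expect_lt(abs(uDynSS(50, DynamicSSParams(dBond = 11))$energy), 1e-3)
})

test_that("triplet repulsion forbids doubly bonded cysteines and is symmetric", {
  # one partner far away: no penalty
  expect_lt(uSSSTriplet(4.0, 50), 1e-3)
  # both partners at the bonded distance: penalty above one well depth
  expect_gt(uSSSTriplet(4.0, 4.0), 11.0)
  expect_identical(uSSSTriplet(3.5, 5.0), uSSSTriplet(5.0, 3.5))
  expect_true(all(uSSSTriplet(seq(1, 10, 0.5), seq(10, 1, -0.5)) >= 0))
})

test_that("the flat-bottom restraint matches its piecewise definition", {
  # interior of the flat region: zero energy and force
  fb <- uFlatBottom(2.4)
  expect_identical(fb$energy, 0)
  expect_identical(fb$force, 0)
  # harmonic branch: U = k (r - r2)^2 at r = 3.5 -> 1.0 kcal/mol
  expect_equal(uFlatBottom(3.5)$energy, 1.0)
  # linear tail force 2 k (r3 - r2) = 8 kcal/mol/A
  expect_equal(uFlatBottom(5.0)$force, -8.0)
  # continuity of U and dU at the switch points
  h <- 1e-9
  for (r in c(1.8, 3.0, 4.0)) {
    expect_lt(abs(uFlatBottom(r + h)$energy - uFlatBottom(r - h)$energy), 1e-6)
    expect_lt(abs(uFlatBottom(r + h)$force - uFlatBottom(r - h)$force), 1e-6)
  }
})

test_that("the restraint tail force is exactly constant", {
  rg <- seq(4.5, 50, by = 0.1)
  f <- abs(uFlatBottom(rg)$force)
  expect_identical(stats::var(f), 0)
  expect_equal(unique(f), 8.0)
})

test_that("forces equal the negative numeric gradient for every mode", {
  top <- withCache("fold24", generateToyFold(
    ToyFoldSpec(24, blocks = data.frame(
      type = c("loop", "helix", "loop", "sheet", "loop"),
      length = c(2, 8, 4, 8, 2)),
      crosslinks = rbind(c(4L, 17L)), seed = 3L)))
  go <- GoParams()
  set.seed(11)
  nb <- nrow(nativeCoords(top))
  for (mode in c("none", "dynamic", "static", "restraint")) {
    redox <- RedoxModel(mode)
    worst <- 0
    for (rep in 1:25) {  # 25 random configurations x 4 modes
      x <- nativeCoords(top) + matrix(rnorm(3 * nb, sd = 0.3), nb, 3)
      e <- totalEnergyForces(x, top, go, redox)
      idx <- sample(3 * nb, 6)
      g <- numericGradient(function(z)
        totalEnergyForces(matrix(z, nb, 3), top, go, redox)$energy,
        as.numeric(x), h = 1e-5, idx = idx)
      worst <- max(worst, max(abs(g + e$forces[idx])))
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("the native conformation is a minimum of the relaxed potential", {
  top <- fold40()
  rx <- relaxStructure(top, redox = RedoxModel("static"), maxSteps = 4000L,
                       fTol = 5e-5)
  expect_lt(rx$gradMax, 1e-3)
  # random perturbations raise the energy
  set.seed(21)
  nb <- nrow(rx$coords)
  e0 <- totalEnergyForces(rx$coords, top, redox = RedoxModel("static"))$energy
  for (rep in 1:5) {
    x <- rx$coords + matrix(rnorm(3 * nb, sd = 0.5), nb, 3)
    expect_gt(totalEnergyForces(x, top, redox = RedoxModel("static"))$energy,
              e0)
  }
})

test_that("overlapping beads are rejected with the pair named", {
  top <- generateToyFold(ToyFoldSpec(20))
  x <- nativeCoords(top)
  x[5, ] <- x[9, ] + 1e-3
  expect_error(goEnergyForces(x, top), "overlapping beads")
})

test_that("mode none has zero disulfide energy; static and dynamic differ only locally", {
  top <- withCache("fold24", generateToyFold(
    ToyFoldSpec(24, blocks = data.frame(
      type = c("loop", "helix", "loop", "sheet", "loop"),
      length = c(2, 8, 4, 8, 2)),
      crosslinks = rbind(c(4L, 17L)), seed = 3L)))
  x <- nativeCoords(top)
  eNone <- totalEnergyForces(x, top, redox = RedoxModel("none"))
  expect_identical(eNone$ss, 0)
  expect_length(eNone$ssPairEnergies, 0)
  eStat <- totalEnergyForces(x, top, redox = RedoxModel("static"))
  eDyn <- totalEnergyForces(x, top, redox = RedoxModel("dynamic"))
  # forces on beads not involved in cysteines are identical across SS modes
  scBeads <- ssmech:::.scBeadMap(top)
  cysBb <- top@cysteines + 1L
  others <- setdiff(seq_len(nrow(x)), c(cysBb, scBeads[cysBb] + 1L))
  expect_equal(eStat$forces[others, ], eDyn$forces[others, ])
  expect_equal(eStat$forces[others, ], eNone$forces[others, ])
  # dynamic mode exposes one energy per cysteine pair
  expect_named(eDyn$ssPairEnergies, "5-18")
})

test_that("restraint mode refuses a topology without crosslinks", {
  top <- generateToyFold(ToyFoldSpec(20))
  expect_error(totalEnergyForces(nativeCoords(top), top,
                                 redox = RedoxModel("restraint")),
               "crosslink")
})

test_that("a shared cysteine at two bonded distances incurs the triplet penalty", {
  # three cysteines, two pairs at the bonded distance sharing the middle one
  spec <- ToyFoldSpec(18, blocks = data.frame(type = "loop", length = 18),
                      crosslinks = rbind(c(2L, 8L), c(8L, 14L)), seed = 1L)
  top <- generateToyFold(spec)
  sc <- ssmech:::.scBeadMap(top)
  x <- nativeCoords(top)
  x[sc[3] + 1, ] <- c(100, 0, 0)
  x[sc[9] + 1, ] <- c(104, 0, 0)
  x[sc[15] + 1, ] <- c(108, 0, 0)
  # move the backbone holders along to keep tether energies comparable
  x[3, ] <- c(100, 2, 0); x[9, ] <- c(104, 2, 0); x[15, ] <- c(108, 2, 0)
  eTot <- totalEnergyForces(x, top, redox = RedoxModel("dynamic"))
  pairU <- uDynSS(4.0)$energy
  # triplet terms centred on each cysteine: (4,4) on the shared one and
  # (4,8) on each outer one
  trip <- uSSSTriplet(4.0, 4.0) + 2 * uSSSTriplet(4.0, 8.0)
  handSum <- 2 * pairU + uDynSS(8.0)$energy + trip
  expect_equal(unname(eTot$ss), handSum, tolerance = 1e-6)
  expect_gt(eTot$ss, pairU)  # double bonding is energetically forbidden
})
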
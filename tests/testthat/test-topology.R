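# Toy-fold generation, PDB loading, disulfide detection and the
# contour-length bound.

test_that("a crosslink-free spec yields a plain chain topology", {
  top <- generateToyFold(ToyFoldSpec(20))
  expect_s4_class(top, "ChainTopology")
  expect_identical(nResidues(top), 20L)
  expect_identical(nrow(top@backboneBonds), 19L)
  expect_identical(nrow(top@crosslinks), 0L)
  expect_identical(length(top@cysteines), 0L)
  # self-avoiding: nonbonded bead pairs at least 2 A apart
  expect_gte(ssmech:::.minNonbondedDistance(top, nativeCoords(top)), 2.0)
})

test_that("toy-fold generation is bitwise deterministic in spec + seed", {
  a <- generateToyFold(fold40Spec(seed = 9L))
  b <- generateToyFold(fold40Spec(seed = 9L))
  expect_identical(nativeCoords(a), nativeCoords(b))
  expect_identical(a@nativeContacts, b@nativeContacts)
  c <- generateToyFold(fold40Spec(seed = 10L))
  expect_false(identical(nativeCoords(a), nativeCoords(c)))
})

test_that("the RNase-A mimic carries its four native disulfides", {
  top <- mimic()
  expect_identical(nResidues(top), 124L)
  expect_identical(nrow(top@crosslinks), 4L)
  d <- ssmech:::.crosslinkDistances(top, nativeCoords(top))
  expect_true(all(d < 5.5))
  expect_identical(anchors(top), c(2L, 123L))
  # detection on the native fold returns exactly the crosslink architecture
  ss <- detectDisulfides(top)
  expect_identical(ss$resi, c(26L, 40L, 58L, 65L))
  expect_identical(ss$resj, c(84L, 95L, 110L, 72L))
})

test_that("a crosslink that cannot be embedded below the cutoff fails naming the pair", {
  # a bonded-well target far beyond the 5.5 A presence cutoff can never be
  # satisfied by relaxation
  expect_error(generateToyFold(fold40Spec(), rBond = 50),
               "unsatisfiable.*9-31")
})

test_that("disulfide detection respects the 5.5 A cutoff and matches greedily", {
  top <- generateToyFold(ToyFoldSpec(
    12, blocks = data.frame(type = "loop", length = 12),
    crosslinks = rbind(c(2L, 9L)), seed = 4L))
  sc <- ssmech:::.scBeadMap(top)
  x <- nativeCoords(top)
  # place the two side-centers at a controlled distance
  setD <- function(d) {
    x[sc[10] + 1, ] <- x[sc[3] + 1, ] + c(d, 0, 0)
    x
  }
  expect_identical(nrow(detectDisulfides(top, setD(5.4))), 1L)
  expect_identical(nrow(detectDisulfides(top, setD(5.6))), 0L)
})

test_that("greedy matching pairs each cysteine with at most one partner", {
  # three cysteines in a row: 1-2 at 4.0, 2-3 at 4.5, 1-3 at 8.5
  spec <- ToyFoldSpec(18, blocks = data.frame(type = "loop", length = 18),
                      crosslinks = rbind(c(2L, 8L), c(8L, 14L)), seed = 1L)
  expect_error(generateToyFold(spec), NA)
  top <- generateToyFold(spec)
  sc <- ssmech:::.scBeadMap(top)
  x <- nativeCoords(top)
  x[sc[3] + 1, ] <- c(0, 0, 0)
  x[sc[9] + 1, ] <- c(4, 0, 0)
  x[sc[15] + 1, ] <- c(8.5, 0, 0)
  ss <- detectDisulfides(top, x)
  expect_identical(nrow(ss), 1L)       # closest pair wins, third stays free
  expect_identical(ss$resi, 3L)
  expect_identical(ss$resj, 9L)
})

test_that("PDB loading keeps one bead per center and applies the altloc rule", {
  fix <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  CYS A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB ACYS A   2       3.800   1.500   0.000  0.40  0.00           C",
    "ATOM      4  CB BCYS A   2       3.800   1.600   0.500  0.60  0.00           C",
    "ATOM      5  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "TER", "END")
  top <- loadStructure(fix)
  expect_identical(nResidues(top), 3L)
  expect_identical(sum(top@beads$kind == "bb"), 3L)
  expect_identical(sum(top@beads$kind == "sc"), 1L)   # exactly one per residue
  sc <- top@beads[top@beads$kind == "sc", ]
  # highest occupancy altloc (B, 0.60) wins
  expect_equal(unname(top@nativeCoords[sc$bead + 1, ]), c(3.8, 1.6, 0.5))
  expect_equal(top@cbeta[2, ], c(3.8, 1.6, 0.5))
  # occupancy tie goes to altloc A
  tieFix <- sub("0.40", "0.60", fix)
  topA <- loadStructure(tieFix)
  scA <- topA@beads[topA@beads$kind == "sc", ]
  expect_equal(unname(topA@nativeCoords[scA$bead + 1, ]), c(3.8, 1.5, 0.0))
})

test_that("PDB round-trip of the synthetic RNase-like structure preserves residues and bonds", {
  top <- mimic()
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(top, f)
  re <- loadStructure(f)
  expect_identical(nResidues(re), 124L)
  ss <- detectDisulfides(re)
  expect_identical(ss$resi, c(26L, 40L, 58L, 65L))
  expect_identical(ss$resj, c(84L, 95L, 110L, 72L))
  unlink(f)
})

test_that("residues without C-alpha are rejected with a warning", {
  fix <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   1.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "TER", "END")
  expect_warning(top <- loadStructure(fix), "C-alpha")
  expect_identical(nResidues(top), 2L)
})

test_that("the extension bound reduces to the contour length for a linear chain", {
  top <- generateToyFold(ToyFoldSpec(20))
  expect_equal(maxExtensionBound(top, matrix(integer(0), ncol = 2),
                                 anchors = c(1, 20)), 19 * 3.8)
})

test_that("a single crosslink shortens the bound by the bypassed backbone", {
  top <- fold40()
  xl <- crosslinks(top)           # 1-based (9, 31)
  i <- xl[1, 1] - 1; j <- xl[1, 2] - 1   # 0-based
  dss <- 4.0 + 2 * 2.0
  expected <- (i + (40 - 1 - j)) * 3.8 + dss
  expect_equal(maxExtensionBound(top, xl, anchors = c(1, 40)), expected)
})

test_that("the bound agrees with exhaustive path enumeration and is monotone", {
  top <- mimic()
  xl <- crosslinks(top)
  n <- nResidues(top)
  for (k in c(4, 2, 0)) {
    intact <- xl[seq_len(k), , drop = FALSE]
    edges <- rbind(cbind(1:(n - 1), 2:n), intact)
    w <- c(rep(3.8, n - 1), rep(8.0, k))
    oracle <- allPathsShortest(n, edges, w, top@anchors[1] + 1,
                               top@anchors[2] + 1)
    expect_equal(maxExtensionBound(top, intact), oracle)
  }
  # monotone non-decreasing as crosslinks are removed
  bounds <- vapply(c(4, 3, 2, 1, 0), function(k)
    maxExtensionBound(top, xl[seq_len(k), , drop = FALSE]), numeric(1))
  expect_true(all(diff(bounds) >= 0))
})

test_that("topology TSV bundles round-trip", {
  top <- fold40()
  d <- tempfile()
  writeTopologyTSV(top, d)
  re <- readTopologyTSV(d)
  expect_identical(nResidues(re), nResidues(top))
  expect_equal(re@crosslinks, unname(top@crosslinks), ignore_attr = TRUE)
  expect_identical(nrow(re@nativeContacts), nrow(top@nativeContacts))
  expect_equal(re@nativeCoords, top@nativeCoords, tolerance = 1e-3)
  unlink(d, recursive = TRUE)
})
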
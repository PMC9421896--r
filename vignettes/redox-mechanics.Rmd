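---
title: "Redox-dependent mechanical unfolding of crosslinked toy folds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redox-dependent mechanical unfolding of crosslinked toy folds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmech)
```

## The model

`ssmech` simulates constant-velocity mechanical stretching of a
coarse-grained protein in which disulfide bonds can break and re-form, so
that the oxidizing or reducing character of the medium becomes a tunable
model parameter.  Each residue contributes one backbone bead (at the
C-alpha position) and, for cysteines, one side-center bead tethered 2 A
away.  Four ingredients make up the potential:

* **Structure-based background.** Harmonic backbone bonds
  (`k = 100` kcal/mol/A^2, `b0 = 3.8` A), 12-10 native-contact wells
  (`eps = 1` kcal/mol between backbone pairs closer than 7.5 A in the
  native structure, with `|i - j| >= 3`), quartic excluded volume
  (diameter 4 A backbone / 3 A side-centers) and cosine pseudo-dihedrals
  (`k = 0.3` kcal/mol) that hold the native fold together.  This is a
  minimal folding background: attractive terms act only between native
  pairs, so unfolding proceeds element by element.

* **Dynamic disulfide double well.** Cysteine side-centers interact through

  $$U(r) = \frac{A}{r^{12}}
         - D_b\,e^{-(r-r_b)^2/2\sigma_b^2}
         - D_c\,e^{-(r-r_c)^2/2\sigma_c^2},$$

  with a deep bonded well at $r_b = 4.0$ A and a shallow contact minimum
  at $r_c = 6.5$ A ($D_c = 1$ kcal/mol, fixed).  The bonded depth $D_b$
  encodes the redox environment: 5.5 kcal/mol for weakly and 11.0 kcal/mol
  for highly oxidizing conditions, values inside the experimentally
  reported 4-22 kcal/mol span.  Changing $D_b$ leaves the contact minimum
  untouched, so the barrier separating a formed from a broken bond
  effectively doubles between the two settings.  The term acts on *every*
  cysteine pair, so non-native bonds can form during stretching.  The core
  coefficient $A = 10^5$ kcal mol$^{-1}$ A$^{12}$ is calibrated so that
  $U(r_b) = -D_b$ within 2 %.

* **Triplet repulsion.** A penalty
  $a\,[s(r_{ki})\,s(r_{kj})]^b$ with the logistic switch
  $s(r) = 1/(1+e^{(r-c)/d})$ activates only when one cysteine has *two*
  partners inside bonding range, enforcing disulfide valence.  Defaults
  ($a = 30$ kcal/mol, $b = 1$, $c = 5.5$ A, $d = 0.3$ A) make a double
  bond cost more than the deepest single well.  All four constants are
  user-tunable.

* **Flat-bottom breaking restraint.** For comparison with force fields in
  which covalent bonds cannot open, `RedoxModel("restraint")` replaces the
  double well on the native pairs by a piecewise restraint: harmonic below
  $r_1$, flat on $[r_1, r_2]$, harmonic on $[r_2, r_3]$ and *linear* above
  $r_3$, where it pulls with the constant force $2k(r_3 - r_2)$.  With the
  published constants ($k = 4$ kcal/mol/A^2, $r_1/r_2/r_3 =
  1.8/3.0/4.0$ A) this force is 8 kcal/mol/A = 555.8 pN, conventionally
  reported as 556 pN.  Those switch distances describe sulfur-sulfur
  separations; because this model's bond coordinate is the side-center
  distance with its minimum at 4.0 A, a restraint-mode `RedoxModel` shifts
  the defaults to 2.8/4.0/5.0 A, preserving $r_3 - r_2$ and hence the tail
  force.  `subtractBreakForce()` removes that constant from the force log
  once a pair has permanently entered the tail, mirroring the standard
  correction to force-extension plots.

Units are kcal/mol, Angstrom and fs throughout; forces are converted at
the reporting boundary with 1 kcal/mol/A = 69.479 pN.  Coarse-grained
pulling speeds are quoted in A per molecular time unit (1 MTU = 4.89 fs)
and correspond to physical speeds after division by the ~1000-fold
coarse-grained acceleration: the 0.0005-0.02 A/MTU grid maps to roughly
0.01-0.4 m/s.

## Dynamics and pulling protocol

Dynamics use the BAOAB discretization of Langevin dynamics with a 0.489 fs
time step, uniform bead masses (110 amu) and friction scaled down by a
factor of 100 from a 5 ps$^{-1}$ waterlike base value to accelerate
sampling, with the thermostat at 300 K (278 K for the temperature
contrast).  With the friction set to zero the scheme reduces to velocity
Verlet and conserves energy to better than 0.1 % over 10^4 steps, which
the test suite checks.  Preparation follows minimization (a FIRE-style
relaxer, 1000 steps) and a seeded 10^4-step thermalization.

Pulling anchors default to the second and second-to-last residues.  One
anchor is tethered harmonically to its native position; the other is
tethered to a point moving at the protocol speed along the initial
anchor-anchor axis (spring constant 1 kcal/mol/A^2, force $= k\,x$).
**Extension** is defined as the current anchor-anchor distance minus its
native value, so it starts at zero and is comparable across modes; the
source experiments never pin this convention down, and the alternative
(spring-point displacement) differs by the instantaneous spring stretch.
Bond states are read from side-center distances with the 5.5 A presence
criterion and a two-saved-frame hysteresis that suppresses flicker at the
boundary; a pair's *final* break is what enters breaking-order statistics,
because fractions can drop and recover several times before disappearing.

## The synthetic toy folds

`generateToyFold()` builds test systems from a block layout (helix-like,
sheet-like, loop).  Blocks become columns on a serpentine grid (helices as
1.5 A-rise spirals, strands as 3.3 A-rise extended runs), loops arc
between columns, crosslinked side-centers are drawn together by restrained
minimization, native contacts are then *measured* from the built
coordinates, and the structure is relaxed to a minimum of the resulting
potential.  Construction is deterministic: identical spec and seed give
bitwise-identical topologies.  Non-crosslinked cysteine pairs are kept
beyond the 5.5 A criterion during construction so the native state
contains exactly the intended bonds.

`rnaseMimicSpec()` encodes a 124-residue mimic of ribonuclease A's
architecture - three helices and seven sheet-like blocks with the four
native crosslinks 26-84, 40-95, 58-110 and 65-72 and anchors at residues
2 and 123.  It reproduces the *architecture* (chain length, element
layout, crosslink nesting), not the crystallographic fold: force-peak
positions and pair-specific breaking order of the real protein are outside
what this toy can show, and the tests only assert properties that survive
that abstraction (redox ordering, peak/break co-location, contour-length
ceilings).  Real structures can be loaded from PDB files instead
(`loadStructure()`), with highest-occupancy altloc selection (ties go to
altloc A) and side-chain heavy-atom centroids as side-centers.

```{r toyfold}
top <- generateToyFold(rnaseMimicSpec())
top
detectDisulfides(top)
```

## What a typical study looks like

```{r smd, eval = FALSE}
redox <- RedoxModel("dynamic", dynamic = DynamicSSParams(dBond = 11))
trajs <- lapply(1:8, function(s)
  runSMD(top, redox = redox,
         protocol = SMDProtocol(speed = 0.02, nSteps = 250000L, seed = s)))
profile <- binForceExtension(trajs)      # 1 A bins, pooled mean +/- SEM
peaks   <- detectPeaks(profile)
bonds   <- bondFractionVsExtension(trajs)
order   <- breakingOrder(trajs)
rep40   <- selectRepresentative(trajs, extension = 40)  # +/- 1 A window
```

The binned profile pools all observations of all trajectories per 1 A
extension bin (mean and standard error of the mean; empty bins are absent,
not zero).  Pooling rather than per-trajectory averaging keeps the SEM
well-defined when trajectories populate bins unevenly.  Representative
conformers minimize the sum of pairwise Kabsch RMSDs inside a +/-1 A
window around a force minimum, with ties broken by the lowest frame id.

## Numerical and design choices

* **Peak detection.** The source analyses read peaks by eye; a
  deterministic rule is required here.  Profiles are smoothed with a
  5-bin moving average, and alternating extrema below a prominence
  threshold (default twice the median per-bin SEM; 50 pN for
  single-trajectory profiles, where the pooled SEM is degenerate) are
  discarded weakest-first.

* **Extension ceiling.** `maxExtensionBound()` computes the shortest
  anchor-anchor path through backbone links (3.8 A each) and intact
  crosslinks.  A crosslink contributes 8 A at residue level: the 4 A
  bonded-well separation plus the two 2 A side-center tethers it hangs
  from.  In static mode the sampled extension stays below this bound
  (minus the native anchor separation) plus a small harmonic-stretch
  allowance; the test pulls 15 A past the bound and checks the 99th
  percentile.

* **Equilibrium-occupancy validation.** The thermostat is validated by
  comparing the sampled distance histogram of an isolated pair against
  direct numeric integration of $r^2 e^{-U(r)/k_BT}$.  At the production
  well depths (9-18 $k_BT$) a single trajectory cannot cross between
  wells on any desk timescale, so the check runs a shallow double well
  (1.5/0.75 kcal/mol) at 300 K with a weak confining link; both wells are
  then thermally accessible and 10^6 saved samples resolve every
  populated bin to within three blocked standard errors.

* **Stability baseline.** The equilibrium stability criterion was
  calibrated once on the 40-residue toy fold and frozen: mean Kabsch RMSD
  of the non-loop core below 3 A over 10^5 static-mode steps (observed
  ~1.9 A).  Terminal loops flap freely by construction and are excluded.

* **Secondary structure proxy.** Element-resolved native-contact
  fractions stand in for DSSP secondary structure: contacts are labelled
  by the element(s) of their residues and counted intact within 1.2 times
  the native distance.  All-atom reconstruction is deliberately out of
  scope.

* **Temperature contrast.** Lowering the thermostat from 300 to 278 K
  shifts force peaks in the same direction as faster pulling, but on the
  40-residue fold the shift is comparable to the 1 A bin resolution; the
  test asserts the direction with a 2 A slack rather than a magnitude.

* **Problem sizes.** The bundled studies use a 40-residue fold (8 seeds
  per condition, three pulling speeds) and the 124-residue mimic (8 seeds
  per redox mode at 0.02 A/MTU, ~250k steps each); these sizes give
  reproducible qualitative contrasts while keeping a full study in the
  minutes range on one core.

## What the tests do and do not show

The suite establishes that the machinery is correct (forces equal
numerical gradients to 10^-4 kcal/mol/A; the integrator conserves energy
and samples Boltzmann; detection, binning, RMSD and selection match
independent oracles) and that the model reproduces the qualitative
redox physics: bonds never break when static, break at force peaks when
the bonded well is deep, and detach from the force landscape when it is
shallow; rupture forces and survival extensions order strictly with the
redox setting; triple disulfides never occur.  Because the toy folds are
synthetic, nothing here validates residue-specific predictions for real
proteins; for that, load an experimental structure and re-run the same
pipeline.

## Limitations

No electrostatics, solvent, or hydrogen bonding; uniform bead masses; a
distance-only disulfide potential (no orientation dependence); single
chains only; no force-clamp mode and no free-energy reconstruction from
the pulling work.
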
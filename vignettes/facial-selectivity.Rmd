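---
title: "Predicting carbene facial selectivity from paddlewheel conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting carbene facial selectivity from paddlewheel conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhface)
```

## The model

A dirhodium tetracarboxylate–carbene complex is a paddlewheel: two Rh
atoms bridged by four carboxylate arms, with the carbene bound apically
to one Rh. The carbene carbon is trigonal and prochiral — an alkene can
attack either its *Re* or its *Si* face — and the four arms carry bulky
imide/aryl blocking groups whose instantaneous positions decide which
face is open. `rhface` operationalises this picture in three layers.

**Arm states.** Each arm is classified by two independent coordinates.
The *side*: the centroid of the arm's imide blocking group is projected
onto the Rh–Rh axis; if it falls on the carbene side of the plane through
the Rh–Rh midpoint (normal along the axis, oriented toward the
carbene-bearing Rh) the arm is α, otherwise β. The *prime*: the torsion
θ about the C~carboxylate~–C~α~ bond is compared with a per-arm
reference θ~ref~, and a wrapped deviation |θ − θ~ref~| inside
[60°, 120°] marks a partial (~90°) rotation, written α′ or β′. A full
180° rotation appears as a side flip with an unprimed torsion, so the two
coordinates never double-count. The four arm states are concatenated and
canonicalized to the lexicographically smallest of the four cyclic arm
rotations under the ordering a < a′ < b < b′ (written α < α′ < β < β′ in
the chemical literature; the package uses ASCII tokens in code and file
output and maps them to Greek only for display). Rotations only — never
reflections — because mirroring the arm order would silently racemise a
chiral complex.

**Face split and distances.** The two prochiral faces are told apart by
the standard CIP construction specialised to this chemotype: looking from
the *Re* side, the substituent priority sequence
Rh > ester carbonyl C > aryl ipso C runs clockwise. The priorities are
hard-coded (Rh wins by atomic number; the ester carbon outranks the aryl
carbon by its (O,O,O) > (C,C,C) duplicated-atom set), which avoids a
general CIP engine at the cost of only supporting this ligand/carbene
family. The carbene plane itself is the least-squares plane through the
carbene carbon and its three substituent anchors rather than an exact
three-point plane, so that slight pyramidalization in simulation
snapshots perturbs the face split smoothly instead of pivoting it about
an arbitrary atom triplet. Each arm's blocking-ring centroid is assigned
a face by its signed offset from this plane, and

d(face) = min over that face's arms of
‖centroid(blocking ring) − centroid(carbene donor ring)‖.

Centroids are unweighted means over the declared heavy ring atoms. A face
with no unambiguous arm yields a missing value, which is reported and
never imputed — imputing a distance would bias the selectivity statistic
exactly where the geometry is least informative.

**Selectivity.** The primary statistic is the paired-frame blocking
probability p(*Re* blocked) = P[d(*Re*) < d(*Si*)] over frames where both
distances exist, ties counting ½. Pairing within frames (rather than
comparing the two marginal KDE modes) respects the frame-level
correlation between the two distances; the KDE modes are reported as
diagnostics. A face is called only when the probability is decisive:
above the decision threshold the open *Si* face is predicted as the
approach face, below one minus the threshold the *Re* face, otherwise no
face. Per-face Gaussian KDEs provide the visual summary, and a
multimodality flag (two or more peaks with a secondary-to-primary height
ratio above 0.2) marks the conformational flexibility that accompanies
weak facial control. The package deliberately predicts only the face
(the ee *sign*) plus qualitative confidence, never an ee magnitude: the
underlying claim is a correlation between steric environments and
selectivity, not a regression.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ambiguity_band` | 0.5 | Å | Blocking centroids closer than this to the carbene plane belong to neither face; near-plane behaviour is otherwise undefined, and such arms are excluded and counted rather than guessed. |
| `primed_window` | [60, 120] | degrees | Captures the "~90°" partial rotation with symmetric margin; deviations above 120° merge into the side classifier via the 180° flip. |
| `decision_threshold` | 0.8 | probability | A face is only called on a 4:1 majority of paired frames; exposed on the CLI. |
| `bandwidth` | Silverman | Å | h = 0.9·min(sd, IQR/1.34)·n^(−1/5); a fixed bandwidth can be supplied. Floor of 0.01 Å on degenerate samples (with a warning). |
| `sphere_radius`, `mesh`, `radii_scale` | 3.5, 0.1, 1.17 | Å, Å, — | Community-standard percent-buried-volume protocol: Bondi radii scaled by 1.17, grid-based occupancy, Rh atoms excluded. |

θ~ref~ defaults to the torsion measured on the first frame when the
topology map omits it, so replicas analysed against one shared topology
map use one shared reference.

## The synthetic generator

`generator_spec()`/`simulate_trajectory()` build an idealized paddlewheel
with planted ground truth: two Rh on the z axis (2.40 Å apart), four
bridging carboxylate arms at 90° spacing, an apical carbene with a
three-atom ester proxy and a benzene donor ring, and one six-membered
blocking ring per arm placed so that (i) the planted arm states are
recovered exactly by the classifier at zero noise and (ii) the planted
face distances d(*Re*)/d(*Si*) are realised exactly as the face minima.
Isotropic Gaussian noise emulates thermal scatter, and an optional Markov
chain (initialised from its stationary distribution) switches the
complex between whole-geometry states to emulate conformational
exchange.

Design notes that matter for interpreting results:

* The internal coordinates are idealizations chosen for robustness, not
  fits to any crystal structure. In particular the torsion-probe levers
  (coordinating-O axial offset 2.0 Å, carboxylate→α spacer 2.6 Å, probe
  stem 4.0 Å) are long enough that 0.15 Å coordinate noise produces only
  ≈8° of torsion jitter, keeping planted ±90° primed states several
  standard deviations inside the [60°, 120°] window.
* A β (away-face) arm cannot simultaneously sit below the paddlewheel
  midplane and close to the donor-ring centroid — the two constraints are
  geometrically contradictory. Planted face distances therefore attach to
  the closest α-family arm of each face, while β rings take fixed
  away-face positions (≥ 8 Å from the donor centroid). Planted distances
  are validated to (1.5, 7.5) Å so they always remain the face minimum.
* What the generator does **not** emulate: real bond-length/angle
  distributions, correlated (collective) motions, solvent structure, or
  any energetics. Passing the recovery tests therefore demonstrates that
  the *analysis chain* is correct and self-consistent — not that any
  particular real catalyst behaves this way. Applying the pipeline to
  real MD output is exactly the intended use, but its validation there
  is empirical, not guaranteed by these tests.

## Numerical choices

* Torsions use the atan2 formulation of the IUPAC convention
  (cis = 0°, range (−180°, 180°]), cross-checked against
  `bio3d::torsion.xyz` in the test suite. Note that a torsion is
  *invariant* under full path reversal — reversing the atom order flips
  both the viewing direction and the endpoint roles, cancelling — and
  changes sign under mirror reflection.
* Face orientation comes from the sign of the summed pairwise cross
  products of the three unit substituent directions; the test suite
  checks it against an independent screen-projection (Newman) oracle on
  randomized fragments.
* Canonicalization compares integer rank sequences, never
  locale-dependent string collation.
* Tie frames (d(*Re*) exactly equal to d(*Si*)) contribute ½ to the
  blocking probability, preserving the antisymmetry
  p → 1 − p under column swap.
* KDE peaks are strict local maxima of the evaluated density; the global
  maximum is always reported, secondary maxima only above 20% of its
  height.
* %V~bur~ counts grid points inside the probe sphere that fall inside
  any scaled atomic sphere; numerator and denominator share one grid, so
  the analytic single-sphere case converges monotonically as the mesh is
  refined (0.2 → 0.1 → 0.05 Å in the tests). A `hemisphere_normal`
  argument restricts the count to one half-sphere for a per-face
  variant; the default is the whole sphere.

## Open design decisions taken

* **Per-frame Re/Si assignment** is not uniquely pinned down by the
  qualitative literature description; the clockwise-CIP construction used
  here is the standard textbook definition, and its mirror antisymmetry
  (reflection swaps every non-ambiguous call) is enforced by tests.
* **The blocking statistic**: the paired-frame probability was chosen
  over mode comparison for robustness to multimodal distributions; both
  agree on rigid ensembles.
* **Arm-to-carbene-carbon distances** (auxiliary descriptor columns
  `d_cc_1..4`) measure from the blocking-ring centroid, consistent with
  the centroid convention of the primary metric.
* **CLI as functions first**: `rhface_main()` and the `run_*()` functions
  carry the pipeline; the installed `inst/scripts/rhface` file is a thin
  wrapper, so everything is testable in-process.

## Problem sizes

The test suite and the acceptance script use ensembles of 2,000 frames
(selectivity recovery, ≈56 atoms per frame), 20,000 frames (Markov
occupancy), 50 frames per arm-state spec across all 24 specs (noisy label
recovery), and 10,000-sample KDE checks. These sizes give binomial
standard errors comfortably below the asserted tolerances (e.g. ±0.02 on
a 20,000-frame occupancy with autocorrelation time ≈4 frames) while the
whole suite runs in about a minute.

## Known limitations

* The CIP priorities are fixed for the Rh > ester > aryl chemotype; a
  carbene whose substituents reorder the priorities needs a different
  orientation rule.
* The conformer taxonomy assumes exactly four arms and one torsion per
  arm; bridged or mixed-ligand paddlewheels are out of scope.
* No free energies, kinetics, or ee magnitudes: the output is a face
  call with a probability, plus flexibility diagnostics.
* The near-plane ambiguity band and the primed window are sharp cutoffs;
  ensembles that concentrate density exactly at a boundary will show
  threshold sensitivity, which is why both are surfaced as parameters
  and recorded in every output file.
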
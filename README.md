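# rhface

Facial-selectivity analysis of dirhodium paddlewheel–carbene
conformational ensembles.

## The problem

Chiral dirhodium tetracarboxylate catalysts (Rh₂(NTTL)₄, Rh₂(TCPTAD)₄ and
relatives) are "paddlewheel" complexes: an Rh–Rh core bridged by four
carboxylate arms whose imide/aryl blocking groups build a chiral pocket
around the reactive carbene. In solution the arms are mobile. Each arm can
sit on the carbene face (**α**) or the opposite face (**β**), and can
additionally rotate partway (~90°, written **α′**/**β′**) about its
C<sub>carboxylate</sub>–C<sub>α</sub> bond, so an ensemble of snapshots
visits conformers such as αααα, αααβ or ααββ. Which prochiral face of the
trigonal carbene carbon — *Re* or *Si* — the arms leave open, and how
*consistently* they leave it open, tracks the sign and quality of the
enantioselectivity the catalyst delivers in carbene-transfer reactions
such as cyclopropanation. Strongly hydrogen-bonding solvents can reshape
the pocket, which is why solvent switches can invert or enhance ee.

`rhface` takes a conformational ensemble (multi-frame XYZ or multi-model
PDB, e.g. MD snapshots) plus a small JSON "topology map" annotating atom
roles, and computes:

* **Conformer classification** — per-arm α/β/α′/β′ states from the imide
  centroid side of the paddlewheel midplane and the torsion
  θ about the C<sub>carboxylate</sub>–C<sub>α</sub> bond (primed when
  |θ − θ<sub>ref</sub>| ∈ [60°, 120°]); canonical 4-arm labels under
  cyclic arm rotation; population tables and flexibility metrics
  (Shannon entropy over conformer fractions).
* **Steric descriptors** — the face-resolved ligand–carbene distances:

  d(*Re*) = min over arms on the *Re* face of
  ‖centroid(blocking ring) − centroid(carbene donor ring)‖, and likewise
  d(*Si*). Faces are assigned by the CIP construction (priority
  Rh > ester C > aryl C clockwise seen from *Re*). Percent buried volume
  (%V<sub>bur</sub>, 3.5 Å sphere, Bondi radii × 1.17) is available as an
  auxiliary descriptor.
* **Selectivity prediction** — kernel density estimates of d(*Re*) and
  d(*Si*), the paired-frame blocking probability
  p(*Re* blocked) = P[d(*Re*) < d(*Si*)], a predicted approach face (the
  *less* hindered one, called only when the probability is decisive), and
  multimodality flags that signal conformational flexibility and hence
  weak facial control.
* **Synthetic ensembles** — an idealized paddlewheel generator with
  planted arm states, planted face distances, Markov state switching and
  Gaussian noise, used throughout the test suite as ground truth.

## Worked example

Simulate a rigid ensemble whose *Re* face is blocked at 3.5 Å while the
*Si* face stays open at 6.0 Å (with 0.15 Å coordinate noise), then run
the full analysis:

```r
library(rhface)

gs  <- generator_spec(d_block_re = 3.5, d_block_si = 6.0,
                      noise_sigma = 0.15, n_frames = 1000, seed = 42)
sim <- simulate_trajectory(gs)

population_table(sim$trajectory, sim$topology)
#> <PopulationTable: 1000 frames (0.0% excluded)>
#>   aaaa     αααα   1.000

report <- facial_bias(descriptor_series(sim$trajectory, sim$topology))
report
#> <SelectivityReport>
#>   p(Re blocked)   : 1.000 over 1000 paired frames (0 missing)
#>   predicted face  : Si (threshold 0.80)
#>   KDE modes       : d(Re) 3.48 A, d(Si) 6.02 A
#>   multimodal      : Re FALSE, Si FALSE

compare_to_experiment(report, 90)$detail
#> [1] "predicted Si-face approach vs experimental ee +90% (consistent)"
```

Every frame is classified as the bowl-shaped αααα conformer; the KDE
modes sit at the planted distances; d(*Re*) < d(*Si*) in every paired
frame, so the open *Si* face is predicted as the approach face — which is
consistent with a reference reaction of positive ee (positive ee meaning
Si-face addition favored). Reflecting the trajectory
(`reflect_trajectory(sim$trajectory, "y")`) inverts the prediction to
*Re*.

The same pipeline runs from a shell via the bundled script:

```sh
RHFACE=$(Rscript -e 'cat(system.file("scripts", "rhface", package = "rhface"))')
Rscript "$RHFACE" simulate --spec spec.json --out sim/
Rscript "$RHFACE" analyze  --traj sim/traj.xyz --topo sim/topology.json \
        --out results/ --ee 90
```

`analyze` writes `labels.csv`, `descriptors.csv`, `populations.json` and
`selectivity.json`, each embedding the exact thresholds used.

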
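# AllosTraj

Trajectory analysis of interdomain allostery and forced unbinding in
modular adhesion receptors.

## What this package is for

P-selectin binds its ligand PSGL-1 through an N-terminal C-type lectin
(Lec) domain, followed by an EGF-like domain and a stalk of
consensus-repeat (CR) modules. The structural story behind its
catch-bond behaviour is allosteric: the bent-versus-extended
orientation of the EGF domain relative to the Lec domain is coupled to
the conformation of the Lec binding-site loop P81–D89 (the R3 loop),
which switches among labelled reference states — S1 (unligated
crystal), S1′ (an equilibrated intermediate) and S2 (ligated crystal) —
and thereby modulates ligand affinity and forced-unbinding behaviour.

Molecular-dynamics work on this system produces equilibration and
steered (pulled) trajectories; AllosTraj is the analysis layer that
turns those frames into quantitative series, for structural biologists
and simulators who want the metrics reproducible and testable apart
from any simulation engine:

* **Domain orientation angles** `θ` about a two-residue hinge: after
  optimal (Kabsch) superposition of each frame onto a reference using a
  rigid-core selection, `θ` is the angle between `v_ref = c(body_ref) −
  c(hinge_ref)` and `v_frame = c(body_frame) − c(hinge_ref)`, where
  `c(·)` is the unweighted geometric centre of the heavy atoms.
* **Loop-state classification**: per-frame RMSD of the R3 loop against
  each reference after rigid-core alignment; a frame is assigned to a
  state when its loop RMSD ≤ 4.0 Å (boundary inclusive), with the S1/S1′
  dual-qualifier tie resolved to S1′, otherwise smallest RMSD.
* **Nonbonded group–group energetics**: `E = S(r)·[ε_ij((R_ij/r)¹² −
  2(R_ij/r)⁶) + 332.0636·q_i q_j / r]` summed over inter-group pairs,
  with the C¹ polynomial switch `S(r)` going from 1 at 10 Å to 0 at
  12 Å, Lorentz–Berthelot combining, charges in e, energies in
  kcal/mol.
* **Forced-unbinding observables**: molecular extension (pulled-atom
  displacement along the fixed→pulled axis), complex separation
  (projected centre distance, or a Euclidean marker distance such as
  fucose–calcium), force-profile peaks, and the dissociation time —
  the first frame at which the receptor–ligand interaction energy
  reaches zero and stays there.

A deterministic synthetic rigid-body generator (`buildToy()`,
`generateEquilibration()`, `generateDissociation()`) emulates this
phenomenology with fully known ground truth, so every metric is tested
by recovery rather than by fiat.

## Worked example

Generate a synthetic equilibration run (EGF reorientation at 6–10 ns,
loop shift S1→S1′ at frame 120, 0.3 Å coordinate noise, a random
global rigid motion every frame), then recover what was programmed:

```r
library(AllosTraj)

toy <- buildToy(seed = 1)
run <- generateEquilibration(toy, syntheticSpec("equilibration", seed = 1))

odef <- OrientationDefinition(toy$selections[["hingeLecEgf"]],
                              toy$selections[["egfBody"]],
                              toy$selections[["lecRigid"]], toy$structure)
ang <- orientationSeries(run$trajectory, odef)
ang[c(1, 61, 81, 101, 121, 201), ]
#>  frame time_ns  angle_deg
#>      1       0  0.6555020
#>     61       6  0.5638287
#>     81       8 30.9209809
#>    101      10 60.4462544
#>    121      12 59.8425760
#>    201      20 61.0593037
```

The angle sits at ~0° through 6 ns, ramps to ~60° by 10 ns and stays
there — the programmed bent→extended hinge schedule, recovered through
the noise and the per-frame global motions (the ~0.5° residuals are the
coordinate noise).

```r
calls <- classifyFrames(loopRmsdSeries(run$trajectory, toy$references))
stateStatistics(calls)
#>  state   n  fraction mean_weight sd_weight
#>     S1 119 0.5920398          NA        NA
#>    S1p  82 0.4079602          NA        NA
transitionDetect(calls, minDwell = 5)
#>  from_state to_state frame
#>          S1      S1p   120
```

Frames 1–119 classify as S1 and the dwell-filtered transition is
reported exactly at the programmed switch frame 120. Passing the
receptor–ligand energy series as `weights` to `stateStatistics()`
yields the per-state energy mean ± SD presentation:

```r
prof <- groupEnergySeries(run$trajectory, "chain A", "chain B", toy$params)
prof
#> EnergyProfile: 201 frames, total -105.2..-81.39 kcal/mol
```

For pulling runs, `generateDissociation()` plus `extensionSeries()`,
`separationSeries()`, `dissociationTime()` and
`forceProfileFeatures()` recover the programmed rupture frame, peak
force and separation-onset extension exactly; see the vignette in
`vignettes/trajectory-allostery.Rmd` for the full account of the
methods and their assumptions.

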
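---
title: "Quantifying interdomain allostery and forced unbinding from trajectories"
author: "AllosTraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interdomain allostery and forced unbinding from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AllosTraj)
```

## The problem

P-selectin is a modular adhesion receptor: an N-terminal C-type lectin
(Lec) domain that carries the ligand-binding pocket and a coordinated
calcium ion, an EGF-like domain, and a stalk of consensus-repeat (CR)
modules. Its interaction with the PSGL-1 ligand (in simulations,
typically the N-terminal sulfoglycopeptide fragment ending at residue
P618) shows catch-bond behaviour, and the prevailing structural picture
ties that behaviour to allostery: the orientation of the EGF domain
relative to the Lec domain (bent versus extended) is coupled to the
conformation of a nine-residue binding-site loop (P81--D89, often
called the R3 loop), which in turn modulates ligand affinity.

Molecular-dynamics studies of this system produce equilibration and
steered (forced-dissociation) trajectories.  Turning those frames into
evidence requires a small set of well-defined metrics, and this package
implements exactly that analysis layer, independent of any simulation
engine:

* **interdomain orientation angles** about two-residue hinges,
* **loop RMSD series** against labelled reference conformations and a
  threshold-based **state classification**,
* **group--group nonbonded interaction energies** (Lennard-Jones +
  Coulomb under a smooth switched cutoff),
* **forced-unbinding observables**: molecular extension, two
  complex-separation measures, force-profile features, and
  dissociation-time detection by the zero-energy criterion.

A deterministic synthetic trajectory generator with machine-readable
ground truth makes the whole pipeline testable at desk scale.

## Containers and conventions

Structures are `MolStructure` objects (one atom table, file order
preserved); trajectories are `MolTrajectory` objects (one topology,
an `nframes x 3N` coordinate matrix, strictly increasing times).
Units are fixed throughout: **Angstrom** for coordinates and
distances, **ns** for times, **kcal/mol** for energies, **pN** for
forces, **degrees** for angles.  Frame indices are 1-based, following
R convention.  Residue numbers are taken verbatim from the input files
(author numbering, e.g. P81, A120, P618); nothing is renumbered.

Atom subsets are named by a small selection grammar
(`resolveSelection()`): predicates `chain`, `resid` (ids and ranges),
`resname`, `name`, `heavy`, `calpha`, `solvent` and `all`, combined
with `not`/`and`/`or` and parentheses.  Selections are pure functions
of (expression, structure); an empty match is an error rather than a
silent empty set.  Because crystallographic and simulation systems may
carry waters and ions, protein selections can exclude them explicitly
with `and not solvent`; the built-in toy selections never contain
solvent, so they do not need the guard.

## Orientation metric

An orientation is defined by four ingredients
(`OrientationDefinition`): the heavy atoms of a two-residue hinge, the
heavy atoms of the oriented domain body, the selection the structures
are aligned on, and a reference structure.  For the EGF domain the
conventional choices are the Lec--EGF hinge (A120 + S121), the main
EGF body (C122--T141), and alignment on the rigid part of the Lec
domain; for the CR1 domain, the EGF--CR1 hinge (C159 + G160), the CR1
body (E161--L217), and alignment on the EGF domain.

Per frame the angle is computed as:

1. superpose the frame onto the reference using the alignment
   selection (optimal proper rigid transform);
2. form the reference vector from the reference hinge centre to the
   reference body centre, and the frame vector from the **same
   reference hinge centre** to the aligned frame's body centre;
3. report the angle between the two vectors in degrees.

Anchoring both vectors at the reference hinge centre makes the metric
a pure function of the body's displacement; a per-frame hinge origin
is available via `perFrameHinge = TRUE` for users who prefer the
alternative convention.  When a trajectory is compared against two
references (e.g. the unligated and the ligated crystal), the same
alignment selection is used for both, which keeps the two angle series
on a common footing.

Because the "rigid part" of the Lec domain is nowhere a fixed list,
it is a configuration key, not a constant; the default used by the
synthetic system is all Lec C-alpha atoms excluding the R3 loop and
the hinge.

## Loop states and classification

Reference conformations are labelled `ReferenceState` objects; the
conventional labels are `S1` (unligated crystal), `S1p` (written S1',
an intermediate captured as a designated equilibration snapshot --
always an input structure, never regenerated internally) and `S2`
(ligated crystal).  Loop RMSD uses `rmsdAfterAlignment()`: the fit is
computed on the alignment selection and the RMSD measured over the
loop only.  The loop RMSD is measured over C-alpha atoms by default;
the selection is configurable where heavier sets are wanted.

`classifyFrames()` applies the rules:

* a frame **qualifies** for a state when its loop RMSD to that state
  is `<= 4.0` Angstrom (boundary inclusive);
* exactly one qualifier: that state;
* both `S1` and `S1p` qualify: call `S1p` (the intermediate takes
  precedence over the unligated crystal);
* any other multi-qualifier combination: smallest RMSD wins (the
  S1/S1' precedence is the only special case, because it is the only
  overlap with an established convention);
* no qualifier: `unassigned`.

The function is total and deterministic, and raising the threshold can
never turn an assigned frame unassigned.  `stateStatistics()` reports
per-state counts, fractions and -- when per-frame weights such as
receptor--ligand energies are supplied -- mean and sample SD (n-1);
empty states report `NA`, not zero, and unassigned frames never enter
weighted statistics.  `transitionDetect()` reads transitions off the
call series with a dwell filter (default 5 frames): a change of state
counts only if the new state persists, with unassigned frames neither
starting nor terminating a dwell.  The dwell filter is the
reproducible analogue of reading transitions off smoothed time series.

## Nonbonded energetics

Interaction energies between two disjoint groups are pairwise sums of

* Lennard-Jones 12-6 in the Rmin convention,
  `eps_ij [(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6]`, with Lorentz--Berthelot
  combining (`eps_ij = sqrt(eps_i eps_j)`,
  `Rmin_ij = Rmin/2_i + Rmin/2_j`), and
* Coulomb `332.0636 q_i q_j / r` (charges in e, r in Angstrom,
  dielectric 1; the constant is stated so results are reproducible bit
  for bit),

both multiplied by the standard C1 polynomial switch
`S(r) = (roff^2 - r^2)^2 (roff^2 + 2 r^2 - 3 ron^2) / (roff^2 - ron^2)^3`
between `ron = 10` and `roff = 12` Angstrom, 1 below, 0 above.  The
switch may be restricted to the van der Waals term
(`switchElec = FALSE` leaves Coulomb plainly truncated at the
cutoff), but the default switches both identically.  This is an
analysis convention, deliberately simpler than the electrostatics used
to *propagate* such simulations (mesh Ewald): a group--group
interaction strength needs a finite-range pairwise definition --- not
least because the dissociation criterion below asks when that energy
*reaches zero*, which is only meaningful for a finite-range sum.
There are no periodic images, no intra-group terms, and no bonded
exclusions (the sums are strictly inter-group).

Per-atom parameters (charge, well depth, Rmin/2) come from a CSV table
keyed by residue and atom name; the force field itself is user input,
not shipped.  `hingeEnergyTable()` applies the two-stage averaging
convention for comparing hinge strengths across replicate
trajectories: time-average within each trajectory first, then mean and
SD across trajectories.

## Forced unbinding

A `PullingSetup` names the held atom, the single pulled atom
(conventionally the ligand's C-terminal P618 C-alpha) and the
protocol: constant force (`cf`, e.g. 300 pN) or constant velocity
(`cv`, e.g. 0.01 Angstrom/ps with a 70 pN/Angstrom spring).  The force
axis is the unit vector from the fixed end to the pulled atom **in the
first frame**, held constant thereafter (the steered-dynamics
convention of pulling along one fixed vector).

* `extensionSeries()`: signed projection of the pulled atom's
  displacement from its first-frame position on the axis (molecular
  extension; frame 1 is 0 by construction).
* `separationSeries()`: projection of the ligand-centre minus
  receptor-centre difference on the axis.
* `markerDistanceSeries()`: plain Euclidean centre distance between
  two markers (e.g. the ligand fucose and the calcium ion) -- the
  second separation convention.
* `dissociationTime()`: the first frame at which the interaction
  energy has reached zero -- `|E| <= zeroTol` (default 0.5 kcal/mol)
  for at least `persistence` consecutive frames (default 5).  A "zero"
  criterion on a fluctuating trace needs both a tolerance and a dwell;
  both are configuration keys, and the event is monotone in the
  tolerance (a larger tolerance never gives a later event).  The
  criterion is applied to the **total** energy by default; vdW-only
  and electrostatics-only event times are reported alongside
  (`unbindingSummary()`), since the components can in principle reach
  zero at different times.
* `forceProfileFeatures()`: the global force maximum and the extension
  at that frame (earliest frame on ties).  For cv runs the force
  series is an input log (`spring x (pull schedule - extension)`), as
  emitted by steered-dynamics engines; the analysis never recomputes
  spring forces from coordinates.
* `replicateStatistics()`: mean and sample SD over replicate runs
  (e.g. six dissociation runs per condition).

## Geometry kernels and numerical choices

* Optimal superposition is the SVD (Kabsch) solution with an explicit
  reflection guard (`det = +1` enforced); the returned RMSD is the
  minimised value.  Degenerate inputs -- fewer than 3 points,
  collinear or coincident sets -- are errors, never a silent answer.
* "Geometric centre" is strictly the unweighted coordinate mean; no
  mass weighting anywhere.
* Angles use the half-angle `atan2` form rather than
  `acos(clamped dot)`, which is accurate near 0 and 180 degrees.
* PDB coordinates are fixed-width with 1e-3 Angstrom resolution;
  round-trip tests assert at exactly that precision.  Delimited
  outputs carry 9 significant digits and a units header.
* Alternate locations: the first altloc is kept; insertion codes are
  rejected (absent from the systems this analysis targets).  Only the
  first MODEL of a multi-model file is read as a structure;
  trajectories require every MODEL to match the topology and name the
  offending MODEL on mismatch.

## The synthetic generator

`buildToy()` constructs a toy system whose architecture mirrors the
receptor--ligand landmark numbering: receptor chain A with one
C-alpha pseudo-atom per residue (Lec 81--120 containing the loop
81--89 and rigid core 90--119; hinge 120--121; EGF 121--158 with body
122--141; hinge 159--160; CR1 161--190; CR2 191--220), ligand chain B
(610--618 plus a FUC marker), and a calcium marker.  The three loop
reference conformations are uniform displacements of the same loop,
pairwise >= 10 Angstrom apart, so the 4.0 Angstrom rule separates them
cleanly, and linear interpolation between them makes expected RMSDs
available in closed form (`|d - d_X|`).  A covering nonbonded
parameter table is emitted with the system.

`generateEquilibration()` applies, per frame: the loop-state schedule;
a CR1 rotation about the EGF--CR1 hinge; an EGF rotation of everything
C-terminal of the Lec--EGF hinge about the hinge centre (both about
fixed axes perpendicular to the respective reference hinge-to-body
vectors, so the recovered orientation equals the schedule exactly when
noise-free); isotropic Gaussian coordinate noise; and a random global
rigid motion.  The default schedules stage CR reorientation before EGF
reorientation before the loop shift, the ordering the analysis is
meant to resolve.  Global motions are **on by default** precisely so
that a pipeline that silently skipped alignment would fail the
recovery tests.

`generateDissociation()` emulates a steered run in two phases: an
intramolecular-extension phase in which the lectin block, loop, ligand
and calcium translate together along the fixed-to-pulled axis
(separation constant, extension growing -- the hinge-opening
phenomenology), then a separation phase in which the ligand recedes
alone.  At the programmed event frame the ligand is displaced beyond
the cutoff plus a safety margin, so the switched interaction energy is
exactly zero from that frame on while remaining far from zero before
it; the rupture-like jump makes the programmed event unambiguous.  The
cv force log is `spring x lag` with a programmed unique peak.  Every
run carries a ground-truth log (schedules, expected calls, event
frame, peak, separation-onset extension), and recovery tests read only
the log.

Defaults are chosen once as the study conditions: 201 frames at 0.1 ns
spacing, coordinate noise 0.3 Angstrom for equilibration (zero for
pulling runs, whose observables are defined in the lab frame), global
motions on for equilibration and off for pulling, dissociation event
at frame 120, separation onset at 25 Angstrom extension, cv peak 200
pN at frame 110, cf force 300 pN, spring 70 pN/Angstrom.  Randomness
is R's Mersenne-Twister with inversion normals under an explicit seed;
outputs are bit-reproducible.

**What the toy does not emulate:** physical dynamics (no inertia,
no correlated fluctuations, no solvent), realistic energetics
(pseudo-atoms with invented parameters), and realistic time scales.
Passing recovery tests therefore demonstrates that the *analysis* is
correct -- metrics recover programmed ground truth exactly, and are
invariant where they should be -- not that any biological conclusion
holds; on real trajectories the force field, sampling and reference
choices dominate.

## Pipeline and configuration

`runPipeline()` dispatches the stages (`synth`, `orient`, `classify`,
`energy`, `unbind`, `report`) against a YAML run config naming the
input paths, the named selections and the thresholds; validation
reports every schema violation at once.  Each run writes CSV artifacts
with a units header, a JSON summary, and a JSON manifest (command,
package version, seed, config and input MD5 checksums) so that a run
can be reproduced and verified byte for byte.  `report` merges
replicate JSON summaries into a mean +/- SD table -- the presentation
layer for replicate statistics.  A thin command-line wrapper is
installed at `inst/scripts/allostery-cli.R`.

## Test problem sizes

The validation suite runs entirely on generated systems: a 151-atom
toy, trajectories of 25--201 frames, 200 random superposition
instances against a 100,000-rotation brute-force search, and 20 noisy
seeds for angle recovery.  These sizes were chosen to exercise every
code path (multi-domain selections, alignment, switching region,
persistence logic) while keeping the full suite interactive.

## Known limitations

* The PDB dialect reader intentionally rejects insertion codes and
  reads only the first altloc; mmCIF is out of scope.
* Energies are inter-group pairwise sums only: no bonded exclusions,
  no periodic images, no polarisation or implicit-solvent terms, so
  absolute values are not comparable to engine-internal energies for
  systems where those matters.
* Correspondence for superposition is by selection order, not by
  sequence alignment; selections on frame and reference must resolve
  to equal counts.
* Transition detection is a dwell filter, not a kinetic model; no
  Markov-state or free-energy machinery is included.
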
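---
title: "Methods: quantifying the membrane positioning of bilayer-anchored cytochrome P450s"
author: "memOrient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying membrane positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memOrient)
```

## The problem

Drug-metabolizing cytochrome P450 (CYP) enzymes are anchored to the
endoplasmic-reticulum membrane by an N-terminal transmembrane (TM) helix,
with their catalytic (globular) domain resting on, and partly dipping
into, the bilayer. The orientation the globular domain adopts above the
membrane controls which substrate-access tunnels open toward the lipid
phase, and closely related isoforms (the CYP 2C9 / CYP 2C19 pair being the
motivating example, at about 91% sequence identity) can adopt measurably
different orientations. Simulation studies of such systems summarize each
trajectory with a small set of geometric observables; `memOrient`
implements those observables as tested, reusable kernels, together with a
synthetic rigid-body generator that provides analytic ground truth so the
entire pipeline can be validated by parameter recovery without any
molecular-dynamics input.

## Orientation observables

All geometry is referred to the membrane normal, taken as the +z axis.
Three axis vectors are built from centers of mass (CoM) of backbone
particles, each end of a segment contributing the CoM of four residues:

* **v1** — from the CoM of the first four residues of the I-helix to the
  CoM of its last four residues;
* **v2** — from the CoM of the first four residues of the C-helix to the
  CoM of the last four residues of the F-helix;
* **v3** — between the terminal four-residue CoMs of the TM-helix.

The observables are then

* **alpha** = angle(v1, z) and **beta** = angle(v2, z), reported
  *unfolded* in [0, 180] degrees — published orientations of this protein
  family include beta well above 90 degrees, so folding would destroy the
  signal;
* **gamma** = angle(v3, z) folded to [0, 90] degrees, since a TM helix is
  an undirected axis;
* **heme tilt** — the angle between the heme plane (least-squares plane
  through the four nitrogens coordinating the iron) and the z axis. This
  is a plane–line angle: with plane normal **n**,
  `heme_tilt = 90 - fold(angle(n, z))`, folded to [0, 90]. A heme lying
  in the membrane plane scores 90 degrees, a heme standing perpendicular
  to the membrane scores 0. This convention reproduces the ranges
  conventionally reported for CYPs (roughly 30–75 degrees);
* **axial distances** — |z(CoM of segment) − z(CoM of all lipid
  particles)| for the globular domain, the linker and the F'–G' region,
  in Angstrom.

Because published beta values are unfolded, a sign convention is needed:
z is oriented so that the globular domain lies *above* the bilayer.
Frames violating this are rotated 180 degrees about x (a proper rotation)
before analysis and the flip is recorded. Whether published analyses
folded the angles for bodies below the membrane plane is not stated
anywhere we know of; this convention is our resolution and is applied
uniformly.

CoM weighting is uniform by default — appropriate for coarse-grained
beads, where one bead does not correspond to one element — and switchable
to element masses (inferred from atom names) for atomistic input.

## Orientation classes

Mean beta maps to a discrete orientation class: **A** below 125 degrees,
**A/B** from 125 to 130, **B** above 130. The A/B interval is closed on
both ends: the class-A definition is strictly "below 125", so boundary
values belong to the intermediate class. The thresholds are configuration
values (`classifyOrientation(beta, thresholds = c(125, 130))`) so the
classifier is reusable for other proteins.

## Convergence and the representative frame

"No further significant change in orientation" has no canonical test, so
the detector is deliberately simple and fully configurable. The series is
tiled into non-overlapping windows (default: 10% of the series length).
The run is converged from the earliest window from which every subsequent
window mean of each monitored field (default beta and the globular CoM
distance) stays within a per-field tolerance of the final window's mean —
defaults 2 degrees for angles and 1 Angstrom for distances, matching the
scale of the standard deviations typically printed for such runs
(roughly 7–14 degrees, 2 Angstrom). At least the penultimate window must
agree with the final one; otherwise the series is reported unconverged
(this is what a monotone drift produces). The detector localizes a
constructed orientation switch to within one window of the true switch
frame; that resolution — one window — is the honest precision of the
method.

The representative frame of a converged window is the frame whose
monitored values (default alpha, beta, gamma, globular and F'–G'
distances) all lie within 1% relative deviation of the window means; ties
are broken by the smallest maximum relative deviation, and if no frame
qualifies the minimizer is returned with an explicit warning flag. The
1% rule mirrors the criterion used to select structures for
back-conversion between resolutions. Relative deviation is |x − mu|/|mu|,
which is why fields with near-zero means (e.g. gamma in a perfectly
upright pose) should be monitored with care; all-NA fields (heme tilt in
a coarse-grained run) are dropped from the monitored set automatically.

## Contact occupancy

A protein residue is in head-group contact in a frame if any of its
particles lies within the cutoff (default 5 Angstrom) of any lipid
head-group particle; tail contacts are counted separately with the tail
particle set. Occupancy is the percentage of analyzed frames with a
contact. Design choices:

* the head set defaults to phosphate atoms (`P`, phosphate oxygens, or
  the `PO4` bead in coarse-grained systems); choline and glycerol atoms
  belong to neither set by default, since head contacts are convention-
  ally defined on the phosphate group. Both sets are configuration;
* hydrogens are excluded from the protein side by default, so the cutoff
  is calibrated on heavy atoms; whether published occupancies used all
  atoms or heavy atoms only is typically unstated, so the switch is
  explicit (`excludeHydrogens`);
* the minimal-image convention is applied in x and y only: the membrane
  is periodic in-plane, and the protein does not wrap in z in slab
  systems;
* the implementation is a vectorized all-pairs evaluation; tests pin it
  to an independent scalar-loop oracle, exactly, so any future spatial
  acceleration must not change results.

## Structural stability metrics

C-alpha (or backbone-bead) RMSD uses optimal rigid-body superposition
(Kabsch, via singular value decomposition, with the reflection guard) so
the reported RMSD is minimal over all rigid transforms. RMSF-derived
B-factors are `B = (8 pi^2 / 3) <|r - <r>|^2>` about the mean structure,
averaged over a residue's selected particles; frames are assumed
pre-superposed (an optional `fit` flag superposes onto frame 1). With
isotropic per-coordinate jitter of variance sigma^2 the expected B is
`8 pi^2 sigma^2`, an analytic limit the tests check at 5% tolerance.

## Sequence comparison

Positional (gap-free) identity is the default for equal-length isoform
pairs; the denominator is the full length. Global alignment (BLOSUM62,
gap open 10, gap extension 0.5, via `Biostrings::pairwiseAlignment`)
handles unequal lengths, with identity over the full alignment length
including gapped columns — the conservative conventional denominator,
stated explicitly because published identity figures rarely state theirs.
The comparison mode and parameters are recorded as attributes of the
result. `differenceReport()` lists mismatches as `X<pos>Y` strings,
optionally restricted to positions of interest such as the
membrane-interface residues.

The package ships no database sequences. `syntheticIsoformPair()`
generates a deterministic pair of 490-residue sequences with 43
substitutions (91.2% positional identity) including the six interface
swaps G46D, K72E, P73R, I99H, S220P, P221T — a synthetic stand-in whose
only purpose is to exercise the comparison code at a realistic
similarity level.

## The synthetic generator: what it emulates, and what it does not

`emitTrajectory(syntheticSpec(...))` builds:

* a rigid scaffold with one backbone bead per residue: an I-helix whose
  axis is the body-frame v1; C- and F-helix stubs placed so the C-start
  to F-end vector realizes v2 at a fixed, known separation from v1
  (default 85 degrees, wide enough to reach the published alpha/beta
  regimes); an F'–G' stub; filler residues on a deterministic sphere; and
  four heme pseudo-nitrogens on an exact square whose plane normal is
  chosen so the initial pose meets the heme-tilt target;
* a planar two-leaflet bilayer of head beads (z = +/- 19 Angstrom, the
  half-thickness of a phosphocholine bilayer) and tail beads between, on
  a square grid with 8 Angstrom spacing (the order of the area per
  lipid), giving a lipid z-CoM of exactly zero;
* a TM helix through the membrane center at the target tilt, joined to
  the posed globular body by a straight linker.

The pose solver computes the rotation from the alpha/beta targets via the
spherical law of cosines; combinations outside the reachable interval
(|alpha − delta| <= beta <= min(alpha + delta, 360 − alpha − delta) for
separation delta) raise an infeasibility error stating the feasible beta
interval. Ground truth is computed in closed form from the rotation
matrix and the constructed coordinates — deliberately *not* through the
analysis kernels — so recovery tests compare two independent routes.
Optional drift interpolates the pose spherically (axis–angle
interpolation of the relative rotation, so intermediate frames remain
rigid-body poses) up to a switch frame and holds it after; positional
noise is iid Gaussian jitter on every coordinate, behind a single
recorded seed.

What the generator does **not** emulate: real helix geometry (segments
are straight bead runs — the terminal-CoM construction is exact either
way), side chains, lipid diffusion and disorder, membrane deformation,
protein flexibility, or any energetics. Passing recovery tests therefore
demonstrates that the geometric pipeline measures what it claims to
measure on rigid bodies under positional noise; it says nothing about
force fields or sampling, which are outside this package's scope.

## Numerical choices

* Best-fit heme plane by least squares (SVD) on the four nitrogens rather
  than the cross product of the two diagonals: negligible difference for
  near-planar hemes, and well-defined for noisy input; collinear
  nitrogens are an error.
* `angle_to_normal` clamps the cosine into [-1, 1] before `acos`.
* Superposition rejects selections with fewer than 3 non-collinear
  points (second singular value below 1e-9 of the first).
* Residue addressing is author numbering from the input file, verbatim;
  the package never renumbers.
* Only orthorhombic boxes are supported; triclinic input is an explicit
  unsupported-format error. Systems this package targets are
  orthorhombic membrane slabs.
* Windows: a scalar in (0, 1] means "last fraction of the series"
  (e.g. 0.9 reproduces the convention of summarizing the production tail
  of a run); a length-2 vector is an explicit frame range; frame indices
  are 1-based throughout, following R convention.
* The C- and F-helix residue ranges that define v2 are not standardized
  anywhere; they are required configuration. The synthetic segment map
  uses 118–135 and 190–209; for real proteins the user must supply the
  ranges from their own structure annotation.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script fixtures use a 4x4 to 6x6 lipid
grid (96–216 lipid beads), a 488-residue protein scaffold, trajectories
of 1–1000 frames, a 48-point orientation-target grid spanning alpha
70–110, beta 100–150, gamma 5–25 and heme tilt 35–70 degrees, and
noisy-recovery runs of 1000 frames at 0.5 Angstrom jitter for three
seeds. These sizes were chosen to exercise every code path at
interactive runtimes; all scale linearly if enlarged.

## Known limitations

* The trajectory container holds coordinates in memory; multi-microsecond
  trajectories should be strided on input. XTC/DCD are not parsed
  natively — convert to multi-model PDB, or construct a `MemTrajectory`
  from coordinates obtained with any reader.
* Convergence detection is a windowed-mean criterion, not a statistical
  test; it is meant to flag gross drift, and its window size is its
  resolution.
* Contact occupancy treats all frames independently; no residence-time
  or hydrogen-bond analysis is attempted.
* The z-flip convention assumes a single protein per system.
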
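# memOrient

Geometric analysis of membrane-anchored cytochrome P450 (CYP) simulation
trajectories, in R.

Mammalian drug-metabolizing CYPs are held at the endoplasmic-reticulum
membrane by an N-terminal transmembrane (TM) helix, with the catalytic
(globular) domain resting on the bilayer. The orientation that domain
adopts — which differs even between isoforms of ~91% sequence identity,
such as CYP 2C9 and CYP 2C19 — shapes the substrate-access tunnels that
open toward the lipid phase. `memOrient` turns a trajectory of such a
system into the standard quantitative description of its membrane
positioning:

* **Orientation angles** from center-of-mass axis vectors: alpha =
  angle(v1, z) with v1 along the I-helix; beta = angle(v2, z) with v2
  from the C-helix start to the F-helix end (both unfolded, [0, 180]°);
  the TM tilt gamma = angle(v3, z) folded to [0, 90]°; and the heme-tilt
  angle between the plane of the four heme nitrogens and the membrane
  normal, folded to [0, 90]°. The membrane normal is +z.
* **Axial distances** of the globular-domain, linker and F'–G' centers of
  mass from the bilayer midplane (Å).
* **Orientation classes** from mean beta: A (< 125°), A/B (125–130°,
  closed), B (> 130°).
* **Convergence detection** (windowed-mean stability) and
  **representative-frame selection** (all monitored values within 1% of
  the window means).
* **Per-residue lipid contact occupancy**, head-group (phosphate) and
  tail contacts counted separately at a 5 Å cutoff, minimal image
  in-plane.
* **Stability metrics**: minimal C-alpha RMSD (Kabsch superposition) and
  RMSF-derived B-factors, B = (8π²/3)⟨|r − ⟨r⟩|²⟩.
* **Isoform sequence comparison**: positional or global-alignment percent
  identity and `X<pos>Y` difference reports.
* A **synthetic system generator** — a rigid pseudo-CYP over a planar
  pseudo-bilayer with closed-form ground truth — so every stage is
  testable by parameter recovery without MD output.

Input is multi-model PDB (natively) or single-frame PDB/GRO; segment
definitions (TM, linker, globular domain, C/F/I helices, F'–G', heme,
lipid head/tail particle names) come from a YAML/JSON configuration.

## Worked example

Generate a synthetic class-B system (the high-beta orientation regime) at
known ground truth, then recover its parameters through the analysis
pipeline:

```r
library(memOrient)

spec <- syntheticSpec(alpha = 100, beta = 137, gamma = 13, hemeTilt = 58,
                      dGlobular = 47, nFrames = 200, jitter = 0.5, seed = 42)
sys <- emitTrajectory(spec)
ser <- orientationSeries(trajectory(sys), segmentMap(sys))
(summ <- summarizeOrientation(ser, window = 0.9))
#   alpha_mean alpha_sd beta_mean beta_sd gamma_mean heme_tilt_mean d_globular_mean
#        99.98     0.51    136.98    0.68      12.97          56.49           47.00
# class: B
```

The windowed means recover the generator targets (alpha 100°, beta 137°,
gamma 13°, globular CoM 47 Å above the bilayer midplane) to a few
hundredths of a degree despite 0.5 Å positional jitter on every particle;
mean beta 136.98° puts the system in class B. Convergence and the
representative frame:

```r
(conv <- detectConvergence(ser))
# ConvergenceReport: converged from frame 1
#   monitored: beta, d_globular | window: 20 frames
rep <- selectRepresentativeFrame(ser, window = c(conv$startFrame, nrow(ser)))
rep$frame        # 161
rep$maxRelDev    # 0.00279  (all monitored values within 1% of window means)
```

Contact occupancy, annotated by region:

```r
occ <- occupancyReport(contactOccupancy(trajectory(sys), segmentMap(sys)),
                       list(TM = c(3, 21), linker = c(22, 49)))
head(occ, 3)
#   residue_number residue_name head_pct tail_pct annotation
# 1              3          GLY      0.5     99.5         TM
# 2              4          GLY      0.0     99.0         TM
# 3              5          GLY      0.0     73.0         TM
```

TM residues sit in the hydrophobic core, so they contact tail beads in
essentially every frame and head beads almost never — the expected
depth profile for an anchored helix.

For real data, point `runPipeline()` at a run-configuration file naming
the trajectory, the segment configuration and the analysis parameters; it
writes `orientation.tsv`, `summary.tsv`, `convergence.tsv`,
`occupancy.tsv`, histogram tables and a JSON manifest. A thin subcommand
wrapper for shell use is installed at
`system.file("scripts", "memorient.R", package = "memOrient")`.

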
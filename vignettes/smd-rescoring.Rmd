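---
title: "Rescoring protein-protein docking poses from scaled-MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring protein-protein docking poses from scaled-MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdrescore)
```

## The problem

Protein-protein docking produces hundreds of candidate bound
conformations ("poses") and ranks them with fast heuristic scoring
functions whose discrimination power is limited: the pose closest to the
experimental complex (the *nearest-native* pose) is rarely ranked first.
A more discriminating alternative is to challenge each candidate with
short molecular dynamics runs under a scaled potential (SMD: all forces
multiplied by a factor lambda < 1, here carried as metadata with default
0.6).  Weakly bound decoys destabilize quickly while near-native poses
tend to keep their interface.  `smdrescore` implements the analysis side
of that protocol: it takes candidate poses and their (real or synthetic)
trajectories and computes interface descriptors per frame, classifies
each trajectory's stability, clusters poses, ranks them, and evaluates
benchmark figures of merit.  Generating MD trajectories is explicitly
out of scope; multi-MODEL PDB is the native trajectory format.

## Descriptors

All calculations exclude hydrogen atoms, and every per-pose descriptor
is the mean over all retained frames of all replica trajectories
(defaults: 3 replicas, 100 frames spaced by 100 ps).

* **iRMSD** (Å): the frame is superposed onto the initial pose over all
  heavy atoms of the *interface residues frozen from the initial pose*,
  and the RMSD is taken over that same atom set.  **iRMSD^B** restricts
  both fit and RMSD to backbone atoms (N, CA, C, O); it is the metric
  used for pairwise pose clustering.  A residue belongs to the interface
  when its solvent-accessible surface area (SASA) drops by strictly more
  than 1 Å² between the isolated binder and the complex.
* **BSA** (Å²): buried surface area,
  SASA(A alone) + SASA(B alone) − SASA(complex), with each binder kept
  in its bound-frame conformation.
* **HBS** (atoms): the number of heavy atoms at the binding interface
  (per-atom ΔSASA > 0.1 Å², parent residue interfacial, both binders
  pooled) whose parent residue is hydrophobic on the Kyte-Doolittle
  scale (KD > −0.4: CYS, MET, PHE, ILE, LEU, ALA, VAL, GLY; KD < −3.2
  hydrophilic: LYS, ASP, GLN, ASN, HIS, ARG, GLU; the rest neutral).
  Unlike the iRMSD residue set, the interface is *recomputed each
  frame*: iRMSD tracks stability of the original interface, HBS tracks
  the composition of whatever interface currently exists.
* **HBS/iRMSD** (Å⁻¹): ratio of the pooled HBS mean to the pooled iRMSD
  mean — high when a pose both keeps its interface and buries many
  hydrophobic atoms.  We use the ratio of averages, not the average of
  ratios: the descriptor is meant to read out the buried hydrophobic
  content while the complex has not yet drifted, and the ratio of means
  is far less sensitive to individual near-zero iRMSD frames.  A pose
  with zero mean iRMSD gets a flagged `Inf` (ranks first); zero HBS
  gives 0.

## Surface model

SASA uses the Shrake-Rupley construction: each atom sphere is inflated
by the probe radius (1.4 Å) and sampled with a deterministic
golden-section spiral point set (default 960 points/atom; the identical
point set for every atom makes results reproducible and
rotation-stable to within ~0.5%).  Neighbor candidates are enumerated
exactly with the analytic overlap cutoff, so the only approximation is
quadrature density.  Atomic radii come from a shipped AMBER-style
heavy-atom table (element fallbacks C 1.70, N 1.55, O 1.50, S 1.80 Å,
...), overridable by file; bit-compatibility with any particular
`amber.siz` file is not claimed.  BSA here is defined on the *accessible*
surface; protocols built on the solvent-excluded surface (SES) report
larger absolute areas.  The descriptor pipeline only needs areas that
are consistent across frames and poses, so the model choice affects
absolute BSA values, not rankings; an SES backend could be slotted in
behind `compute_sasa()` if absolute compatibility were needed.

## Stability classification

Per trajectory, from the mean iRMSD and mean BSA:

| condition | class |
|---|---|
| mean iRMSD ≤ 4.0 Å | `conserved` |
| mean iRMSD > 14 Å **and** mean BSA < 200 Å² | `unstable` |
| mean iRMSD > 5.5 Å otherwise | `new_interface` |
| 4.0 Å < mean iRMSD ≤ 5.5 Å | `ambiguous` |

The 4.0–5.5 Å band is deliberately a first-class output: protocols
resolve it by visual inspection, and this package never silently coerces
it.  "The iRMSD stabilizes before the end of the run" is quantified as:
standard deviation of the final 20% of the iRMSD trace ≤ 1.0 Å; a lost
interface without a stabilized tail is still `new_interface` but carries
a `"low"` confidence attribute.  `unstable` requires *both* conditions
(conjunctive reading).  A pose's class is the majority vote of its
replicas, ties resolved to the worst class
(unstable < new_interface < ambiguous < conserved).  Poses of every
class are ranked; classification is reported alongside, never used to
filter.

## Clustering and selection

Pose redundancy is removed with greedy neighbor-count (Daura)
clustering on the pairwise iRMSD^B matrix at a 4 Å cutoff: repeatedly
take the pose with the most neighbors within the cutoff as a cluster
medoid and remove the cluster.  Ties on neighbor count go to the lowest
pose index — reference implementations differ here, and a fixed rule
makes output deterministic.  The pairwise interface for entry (i, j) is
the union of the two poses' own interface residue sets.  Benchmark
admission applies two criteria: (1) some cluster medoid lies within 4 Å
backbone iRMSD of the reference, and (2) such a medoid appears among
the 20 best-scored clusters.

## Ranking and figures of merit

Poses are competition-ranked per descriptor (ties share the lowest
applicable rank, the next rank is skipped); iRMSD and external docking
scores rank ascending, BSA, HBS and HBS/iRMSD descending.  Three
figures of merit compare a descriptor's ranking with the known
nearest-native pose: **min-to-min** (the nearest-native is ranked
first), **within-sigma** (its descriptor value is within one descriptor
standard deviation of the best-ranked pose's value — evaluated on
values, not ranks), and **first-quartile** (rank ≤ floor(n/4); with the
pose counts that occur in practice, 20 and 14, the floor/ceiling choice
does not change headline counts).  Sigma per descriptor is the maximum
per-frame standard deviation over the interface-conserving
(`conserved`) trajectories; calibrated defaults are 10 (external
score), 0.5 Å (iRMSD), 50 Å² (BSA), 1.5 atoms (HBS) and 1.6 Å⁻¹
(HBS/iRMSD).  Bundled with the package
(`load_benchmark_ranks()`, `load_benchmark_stability()`) are the
per-system summary tables of a published eight-system benchmark, used
as worked-example inputs for these tally operations.

## The synthetic generator

Real SMD trajectories of docking poses are not reproducible at desk
scale, so `make_toy_dimer()` / `synthesize_trajectory()` /
`make_benchmark_ensemble()` provide controlled stand-ins:

* **Toy dimers**: two rigid mini-chains, idealized backbone plus pseudo
  side chains carrying one centroid atom per real side-chain heavy atom
  (so HBS arithmetic matches real residue types).  Chains sit on
  parallel planes 8.5 Å apart; requested contact residues extend their
  side chains toward each other to a 4 Å tip gap, all others point
  away.  The construction is validated post hoc: exactly the requested
  residue pairs are within the 5 Å contact cutoff, anything else is a
  placement error.
* **Behaviors** (binder A fixed, binder B rigid): `conserved` —
  per-frame Gaussian translation jitter (rms 0.3 Å by default) around
  the initial pose; `drift` — cumulative rotation about the interface
  normal through B's centroid (8°/frame) until a contact pair absent
  from the initial interface appears, then hold with jitter; `unbind` —
  linear translation along the separation axis (0.6 Å/frame).  All
  generators are pure functions of their seeds, with deterministic
  arithmetic fan-out over (base seed, pose, replica).
* **Calibration.**  Conserved runs with jitter ≤ 0.5 Å give mean iRMSD
  well below 4 Å.  For unbinding, the class `unstable` needs mean iRMSD
  > 14 Å; a linear separation at rate r over 100 frames has mean
  displacement 49.5·r, and after least-squares superposition over a
  two-sided interface set the RMSD is at most half the displacement
  (exactly half for equal-sized sets), so rates below ~0.57 Å/frame
  *cannot* reach the threshold — hence the 0.6 Å/frame default, which
  lands at mean iRMSD ≈ 14.8.
* **Ensembles**: 20 poses, one designated near-native with three bulky
  hydrophobic contact pairs (conserved behavior), decoys with two
  contacts, one mildly hydrophobic and one polar, cycling through
  drift/conserved/unbind behaviors.  Synthetic external docking scores
  are drawn uninformatively (uniform), providing a built-in
  random-ranking baseline.  What passing recovery tests on these
  ensembles shows is that the descriptor pipeline faithfully reads out
  *designed* contrasts; it does not show that real docking decoys are
  this well separated — real interfaces flex internally, pack far more
  atoms, and blur every contrast used here.

## Numerical choices

* Quadrature density: 960 points/atom by default (isolated-sphere error
  ≲ 0.5%).  The 50-seed recovery study runs at 144 points/atom: the
  study compares several-fold descriptor contrasts, for which ~2%
  area error is irrelevant, and the full study then completes in
  minutes on one CPU.
* Trajectory grid: grid times are spacing × (1..n); each grid time
  takes its nearest frame, earlier frame on ties; a trajectory with no
  more frames than requested is used as is.
* Superposition: SVD-based Kabsch with proper-rotation correction;
  degenerate (collinear) inputs are an error.  Interface atoms missing
  from a frame are dropped pairwise up to 5% of the set, beyond that an
  error lists them.
* PDB conventions: residue identity is (chain, resid, insertion code),
  numbering never rewritten; altloc records other than ''/'A' are
  dropped; MSE aliases to MET, other non-standard residues are a
  classification error unless a default class is supplied.
* Strictness: the 1 Å² residue and 0.1 Å² atom thresholds are strict
  (`>`); exposure uses strict `>` with epsilon 0.

## Limitations

* BSA absolute values are SASA-based (see above), and the shipped radii
  are an AMBER-style set, not a byte-for-byte copy of any specific
  radii file.
* The per-frame HBS pools both binders; per-binder counts are available
  from `interface_analysis()` but the headline descriptor is pooled.
* The generator produces rigid-body motion only — no internal
  flexibility, no force field, no solvent; its trajectories exercise
  the analysis code, not the physics.
* Whether a pairwise pose distance should use a fixed reference
  interface or per-pair interfaces is a convention choice; this package
  uses the per-pair union.
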
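---
title: "Quantifying peptide engagement with a ganglioside raft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peptide engagement with a ganglioside raft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftpath)
```

## The problem

Gangliosides such as GM1 cluster with cholesterol into lipid-raft
microdomains whose protruding sugar headgroups form the first binding
surface a membrane-active peptide meets.  A peptide that inserts between
those headgroups can occupy the raft and deny access to competing
proteins — for instance an amyloidogenic peptide whose membrane insertion
would otherwise nucleate Ca^2+^-permeable pores.  Molecular-dynamics
trajectories of such systems are information-rich but unwieldy: the
questions a raft-binding study actually asks are a small set of scalar
and time-series summaries.  `raftpath` computes those summaries:

* **Protrusion benchmarks** — how far each part of the ganglioside
  headgroup (ceramide anchor, glucose, inner galactose, GalNAc, terminal
  galactose, sialic acid) protrudes along the membrane normal, averaged
  over molecules and time.  These calibrate everything else: a residue
  is "buried to the glucose level" when its z-coordinate drops below the
  glucose benchmark.
* **Burial depth and travel trails** — the side-chain centre of mass of
  named residues along z, and their 3D paths across the raft surface.
* **Raft zonation and differential solvation** — a partition of the
  ganglioside cluster into three equal-membership zones (far periphery,
  centre, peptide-accommodating periphery) with per-zone water-contact
  counts and solvent-accessible surface area (SASA).
* **Stage segmentation** — labelling of the trajectory into early
  (central attachment), intermediate (detachment and migration) and late
  (stabilised peripheral binding) stages from per-zone contact occupancy.
* **Competition metrics** — for two-peptide systems: who touches the
  gangliosides first, how intramolecular U-folding masks aromatic
  residues, and how peptide binding spreads the sugar headgroups apart.

## Coordinate conventions and the z reference

Coordinates are Angstrom, the membrane normal is +z, frames carry times
in ns.  Two z conventions are supported everywhere a depth is reported:
relative to the **bilayer centre** (the midpoint between the mean z of
upper- and lower-leaflet headgroup-reference atoms: phospholipid
phosphorus, the topmost ceramide atom of each ganglioside, sterol
oxygen), or **absolute box z**.  Published depth plots do not always
state which convention they use — burial values in the 40–50 Å range are
natural in box coordinates but not relative to a bilayer centre — so the
`z_reference` flag makes either explicit.  The synthetic reference
system plants its bilayer centre at 35 Å so the two conventions differ
by a known constant.

## Protrusion and burial

The per-moiety protrusion statistic is computed in a fixed order:
maximum z over a molecule's moiety atoms (heavy atoms only — hydrogens
add jitter without chemical meaning), then mean over molecules within a
frame, then mean over frames.  Other orders (e.g. max over the pooled
cluster) weight large molecules differently; the chosen order treats
each ganglioside as one observation of headgroup extension.

Burial uses the mass-weighted centre of mass of a residue's side-chain
heavy atoms; the backbone is excluded because burial between headgroups
is a side-chain phenomenon, and an all-atom mode exists for residues
without side-chain heavy atoms.  The scalar burial value is the plain
arithmetic mean over the analysed window (full trajectory by default; a
stage window can be requested).  When a burial series is compared
against a moiety benchmark, a frame in which the two are exactly equal
counts as *reaching* the moiety — a closed boundary, consistent with
every other cutoff in the package.

## Zonation and solvation

The raft partition is the one genuinely free design choice in the suite:
"three equal parts containing the same number of molecules" does not
prescribe a geometry.  `partition_raft()` projects each ganglioside's
time-averaged lateral centre of mass onto the axis running from the raft
centroid towards the peptide's mean lateral position (by default over
the final quarter of the trajectory, where the stabilised binding site
lies), then cuts the ranking into tertiles.  This reproduces three
parallel bands across the cluster with the peptide-accommodating band at
one edge.  When the molecule count is not divisible by three the
remainder goes to the centre zone; rank ties break by molecule id so the
partition is deterministic.

Water contacts count **distinct water molecules** with any atom within
2.5 Å of any target atom, under orthorhombic minimum-image distances.
The 2.5 Å default is hydrogen-bond-like, which is why water hydrogens
participate by default (`water_atoms = "oxygen"` restricts to oxygens).
The count is implemented with a cell-list kernel and is validated in the
test suite against a brute-force all-pairs oracle to integer equality.

SASA is Shrake–Rupley: van-der-Waals spheres (Bondi radii) inflated by a
1.4 Å water probe, sampled with a deterministic Fibonacci sphere lattice
of 960 points per atom so results are bit-reproducible — no RNG enters
any analysis routine.  Every other atom in the system occludes the
target group, so a zone's SASA is its exposed surface in context.  The
single-sphere case is exact to the closed form within 1 %, and arbitrary
clusters agree with a 10^5-point random-direction refinement oracle
within 2 %.  Triclinic boxes are rejected with a clear error; the
minimum-image code is orthorhombic only.

## Stage segmentation

Segmentation is threshold-plus-hysteresis rather than a penalised
changepoint model: with three scripted stages and contact occupancies
that saturate when bound, a transparent rule with three parameters
(smoothing window 21 frames, minimum occupancy 5 contacts, persistence
10 frames) is adequate and auditable.  Per-zone contact counts are
smoothed with a centred moving average; the early stage opens at the
first persistent epoch of centre-zone occupancy, `t_detach` at the first
persistent loss of it, and `t_stabilize` at the first frame from which
the near-periphery stays occupied for at least 80 % of the remaining
frames.  Because smoothing displaces a step edge by up to half a window,
each boundary is then refined to the nearest *raw*-occupancy crossing
(itself required to persist) within half a smoothing window — boundaries
land on the transition frame, not the smoothing shoulder, and isolated
noise frames cannot capture them.  A trajectory with no persistent
attachment yields all-`unbound` labels and a warning, not an error;
permanent central binding yields `t_detach` at the trajectory end and no
late stage.

## Contacts, interaction types, stacking

Atom–atom contacts use a 3.0 Å closed-boundary cutoff with all atoms
(hydrogens included) — 3 Å is sub-van-der-Waals for heavy-atom pairs, so
a heavy-only reading of that cutoff would find almost nothing.
Interaction classification tags a contact *hydrogen bond* when both
atoms are N/O within 3.5 Å and a donor hydrogen satisfies a D–H···A
angle of at least 120°; when the structure carries no hydrogens the
angle test is skipped and a warning record kept.  *Electrostatic* means
oppositely charged formal-charge groups within 4.0 Å (lysine/arginine
ammonium and guanidinium, carboxylates including the sialic-acid
carboxylate, monatomic ions).  A salt bridge legitimately carries both
tags; contacts earning neither are van der Waals.  Ring stacking scores
a residue pair per frame by ring-centroid distance (≤ 5.5 Å) and acute
interplanar angle (≤ 45°, plane fitted by SVD).

## Competition metrics

First contact is the first frame opening a run of at least 3 frames with
any peptide–ganglioside contact; the persistence filter discards
single-frame grazing touches.  An *intramolecular* contact requires a
sequence separation of at least 3 residues, excluding trivially bonded
neighbours.  The masking fraction of an aromatic residue is the fraction
of frames with at least one intramolecular contact and zero ganglioside
contacts — the U-fold signature.  Headgroup spread is the mean, over
gangliosides, of the lateral (xy, minimum-image) distance from each
molecule's sugar-headgroup centre of mass to its nearest neighbour.

## The synthetic reference system

Real all-atom trajectories of raft–peptide systems cannot be regenerated
at desk scale, so validation rests on a generator whose every output
quantity is planted.  `synthetic_spec()` describes the reference
conditions; `generate_system()` builds the topology, the trajectory and
a `truth` list.  The defaults are the package's study conditions:

* 24 GM1-like gangliosides on a lateral lattice (8 Å spacing) with
  sterols at 1:1, a 36-lipid phospholipid ring defining two leaflets
  (half thickness 18 Å), bilayer centre at 35 Å in a 120 × 120 × 100 Å
  box; 500 frames at 0.12 ns (≈ 60 ns).
* Moiety ceilings 18 (ceramide) < 23 < 26 < 28 < 30 < 31 Å (sialic acid)
  above the bilayer centre, each moiety a 3–5 atom pseudo-group with
  real element labels so masses and SASA radii resolve.
* A 12-residue peptide with tracked aromatics Y6, H9, H10 descending
  from 12 Å above the raft, attaching centrally at 1.2 ns, detaching at
  30 ns, migrating around the raft edge, and binding the periphery from
  45 ns.  Planted full-trajectory burial averages are 41.36 (Y6), 46.30
  (H9) and 47.10 Å (H10) in box z.
* Gaussian positional noise: independent per-atom jitter for lipids
  (SD 0.5 Å) and waters (0.3 Å); peptide residues move as rigid bodies
  with SD 1.0 Å translations plus 0.3 Å per-atom jitter.  The H9/H10
  pair shares one translation (a rigid aromatic sub-unit), which keeps
  ring-geometry observables meaningful at 1 Å noise.
* Differential solvation is planted through shell waters tethered near
  each zone's sugar tops: the centre zone receives half the far
  periphery's density and the accommodating periphery 1.2×; the centre
  zone is also laterally compressed (spacing factor 0.8) and the near
  zone expanded (1.2), so packing, water exposure and SASA order the
  zones consistently.
* H10 stacks on H9 in an exactly-counted 60 % of late-stage frames;
  exact-count schedules (rather than per-frame Bernoulli draws) are used
  for all planted fractions so recovery tolerances reflect measurement
  error, not schedule sampling error.

`synthetic_competition_spec()` describes the two-peptide variant: four
gangliosides on a square patch, a 14-residue U-folding competitor whose
aromatic H13/H14 are masked in 70 % of frames, first contacts planted at
1.2 ns (designed peptide) and 4.0 ns (competitor), and a matched
peptide-free system whose headgroups pack at 7 Å instead of 9 Å.

What the generator does **not** emulate matters for interpreting green
tests: there is no force field, no excluded volume, no water dynamics,
no conformational entropy — kinematics are scripted and noise is
Gaussian.  Passing tests therefore demonstrate that the estimators
recover planted structure at realistic noise amplitudes and sampling
densities, not that the biology of any real trajectory is reproduced.
Quantities that depend on fine atomic packing (absolute SASA values in
particular) are internally consistent but not comparable to all-atom
simulations.

## Problem sizes and runtime choices

The validation suite analyses the full 500-frame reference system for
burial, staging and zonation; per-zone solvation and late-stage SASA use
every fifth frame (100 and 25 frames respectively), which stabilises the
means while keeping the Shrake–Rupley evaluation cheap.  The
boundary-recovery study repeats the full pipeline over 20 seeds with
stage boundaries varied ±10 ns (keeping at least 5 ns between them, the
minimum for an intermediate stage to exist).  Oracle-equality checks run
on 20 random frames of a reduced 60-frame system whose ganglioside group
still exceeds 100 atoms.

## Known limitations

* Orthorhombic periodicity only; triclinic boxes are rejected.
* Trajectory formats are DCD and multi-model PDB (XTC is not read);
  GRO and PDB topologies.  Frame times are synthesised from a stride
  argument rather than trusted from binary headers.
* Leaflet assignment is sign-based and assumes a roughly planar bilayer;
  strongly curved membranes would need a local reference surface.
* Moiety annotation is name-pattern-driven.  The defaults cover the
  generator's scheme and common carbohydrate naming, but force fields
  differ — the rules are user-overridable and unmatched atoms are
  reported rather than silently dropped.
* The segmentation rule assumes one attach–migrate–rebind cycle, which
  is the scripted scenario it was designed for; repeated binding cycles
  would be summarised by their first occurrence.
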
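---
title: "Methods: phosphoinositide binding-site mapping for symmetric membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphoinositide binding-site mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipsites)
```

## Scope and model

`pipsites` post-processes two kinds of evidence about where
phosphoinositide (PIP) headgroups bind a rotationally symmetric membrane
protein: sets of rigid-docking poses, and coarse-grained (CG) trajectories
with lipid headgroup beads. It does not dock, does not run dynamics, and
does not predict protonation or membrane placement: the structure is
assumed already oriented in a membrane frame with +z as the bilayer
normal, the way membrane-orientation servers emit it. The membrane frame
(midplane height and inner-leaflet headgroup boundary) is therefore a
configuration input, not a computed quantity; the fixture default is a
midplane at z = 0 with the intracellular boundary at −20 Å, a typical
half-thickness for a phospholipid bilayer.

All coordinates are Cartesian Å. The dual-cutoff radii are specified in
nm, the unit in which CG contact cutoffs are conventionally quoted, and
converted internally. Residue identity is the pair (chain, author residue
number); insertion codes are rejected with an explicit error rather than
silently renumbered.

## Pose reduction, acceptance and symmetry

A docked headgroup truncated at the glycerol C1 carbon is reduced to
three centroids: the C1 atom, the unweighted mean of the six inositol
ring carbons, and an anchor phosphate at the inositol 3/4/5 position.
This reduction keeps exactly the degrees of freedom that distinguish
binding sites — where the ring sits, which way the tail points, and how
the phosphate is presented — while discarding conformer detail.

Three choices here were genuinely open and are fixed as follows:

* **Tail direction.** The tail vector runs from the inositol centroid to
  the glycerol C1, the direction in which the acyl chains continue in the
  full lipid. The elevation φ = asin(t_z/|t|) is measured against the
  membrane plane; a pose is accepted iff φ ≥ −tolerance. A pose pointing
  its tail into the cytoplasm cannot belong to a membrane-embedded lipid.
* **Tolerance.** "Parallel or toward the membrane" needs a numeric
  tolerance below exact parallelism; the default is 15°, a knob in the
  configuration because no single value is canonical. Acceptance depends
  only on t_z and |t|, so it is provably invariant under any rotation
  about z — the filter cannot disagree between symmetry images.
* **Anchor for multiply phosphorylated species.** When several of the
  3/4/5 phosphates exist the lowest-numbered one is the anchor; for PI,
  which has none, the C4 hydroxyl oxygen is used. Both are editable in
  the atom-group map (`default_atom_group_map()`).

To pool equivalent sites on different subunits of a C_n assembly,
accepted poses are rotated by multiples of 360°/n about z into the
reference wedge, chosen as inositol azimuth in [0°, 360°/n). The
rotation count is accumulated on the pose vector so the reduction is
idempotent and the recorded k always maps the original pose onto its
wedge image; contact searches re-apply it to the full atom set. A pose
whose inositol centroid lies exactly on the symmetry axis has no defined
azimuth and is reported as an error rather than assigned arbitrarily.

## Clustering and representatives

Poses are clustered by single-linkage agglomeration at a 15 Å cutoff.
"Centroids within the cutoff" is read strictly: two poses are directly
linked only if each of the three corresponding centroid pairs is within
15 Å (equivalently, linkage distance = max of the three distances). The
looser reading — inositol centroid only — is available as
`mode = "inositol_only"`; since max-of-three dominates the inositol
distance, the strict mode can only produce more clusters, never fewer.
Single linkage was chosen because the procedure is defined by a cutoff,
not a cluster count, and cutoff-thresholded single linkage is exactly
"merge anything connected by links within the cutoff".

Each cluster's representative is its medoid on the inositol centroid
(minimum summed distance to the other members), with ties broken by the
smallest pose id. Cluster order (descending size, then smallest member
id) and all tie-breaks are fixed so outputs are byte-reproducible and
invariant under permutation of the input.

Contacts use heavy atoms only, with the 4 Å boundary inclusive. Whether
the original analyses included hydrogens or the exact boundary is not
determinable from typical methods prose; these choices are documented
here rather than claimed as a reproduction of anyone's settings.

## The lipid-accessible surface

The count of residues forming the lipid-accessible surface of the inner
leaflet depends on an accessibility definition that published work
rarely states. The definition fixed here: a residue belongs to the
surface when its side-chain heavy-atom centroid lies in the slab between
the intracellular boundary and the midplane, and its side-chain relative
solvent accessibility is ≥ 0.20. Relative accessibility is computed
with a Shrake–Rupley surface (probe 1.4 Å, 192 deterministic
Fibonacci-lattice sphere points per atom) as side-chain SASA in the full
structure divided by the SASA of the same atoms extracted in isolation.
Normalizing against the residue's own isolated side chain rather than a
tabulated per-amino-acid maximum keeps the measure defined for arbitrary
(including synthetic) residue compositions. Published per-subunit counts
obtained with other definitions are not expected to be reproduced
exactly; on a C_n-symmetric input the returned set is exactly symmetric
across chains, which is the property the downstream normalization needs.

## Dual-cutoff contacts and binding sites

A lipid–residue contact event begins at the first frame where the
minimum distance between any headgroup bead and any residue particle is
≤ r_on (0.5 nm) and persists while it remains ≤ r_off (0.8 nm); the
event ends the frame before the distance first exceeds r_off. The
hysteresis suppresses rattling at a single threshold. Setting
r_on = r_off recovers plain thresholding, which the tests exploit as an
equivalence oracle. Occupancy is the percentage of frames with ≥1 lipid
in contact, counted once per frame regardless of how many lipids are
bound.

Binding sites are built from residue commonality: residues i and j are
joined when the *same* lipid molecule is simultaneously in contact with
both (within the r_off contact state) in at least 5% of frames, and
connected components with ≥2 residues become sites. This deterministic
co-contact/connected-components construction was chosen over stochastic
community detection for testability; the 5% edge threshold is a
configuration knob. Site occupancy uses union semantics, so it is never
below the best member residue's occupancy. Density maps are plain 2D
histograms of a reference bead per lipid (first bead by default) on a
grid covering the xy bounding box, divided by the frame count; binned
mass is conserved exactly.

## Synthetic fixtures and what passing tests show

The generators produce: toy C_n oligomers with exact rotational symmetry
(idealized three-atom residues on a ring of helical subunits spanning
z ∈ [−25, 25] Å); planted pose sets (idealized hexagonal headgroup
templates scattered with σ = 2 Å around chosen centers, a configurable
fraction tail-flipped, each pose optionally moved to a random symmetry
image); and scripted dwell trajectories where lipids alternate
far-from-protein diffusion with dwells that park one bead ~2 Å from each
planted site residue. Dwell lengths are geometric, or fixed-length when
a deterministic duty cycle is wanted (e.g. 20 bound/30 free plants a 40%
occupancy exactly). Every generator takes one seed and is
bit-reproducible.

These fixtures emulate the *logical* structure of docking output and CG
trajectories — cluster geometry, orientation statistics, dwell/occupancy
bookkeeping — not their physics. Passing the planted-truth suites shows
the pipeline recovers known ground truth under clean separation (centers
≥ 3× the cluster cutoff apart; sites on residues spaced beyond the inner
cutoff); it does not show that real, overlapping, noisy binding sites
are resolved, nor anything about force-field realism. Test problem sizes
(≤ 300 poses, ≤ 2000 frames, ≤ 6 lipids) were chosen as the smallest
scales at which the statistical checks (binomial acceptance fractions,
dwell-mean estimates over ≥ 200 events) are meaningful.

## Numerical and degenerate-input conventions

* Distances and cutoffs compare inclusively (≤), so a contact at exactly
  4.0 Å counts.
* Wedge assignment at an exact wedge boundary goes to the lower wedge
  (floor on the azimuth), matching the half-open [0°, 360°/n) interval.
* Empty accepted sets are results, not errors: the docking summary
  reports zero clusters and empty tables and the workflow logs a
  warning; zero-event trajectories yield empty site tables.
* Multi-model files presented to the single-structure reader, poses with
  missing mapped atoms, degenerate membrane frames, on-axis inositol
  centroids, and r_on > r_off all raise explicit errors naming the
  problem.

## Limitations

* Trajectory input is multi-model PDB; compressed CG trajectory formats
  (XTC/GRO) are not read because no installed dependency parses them —
  convert to multi-model PDB first. The `frame_series` contract is
  format-agnostic, so an additional reader can be slotted in without
  touching the analyses.
* The site detector is a deterministic re-specification of
  commonality-based clustering, not a clone of any particular
  community-detection tool; on entangled sites it can merge what a
  modularity optimizer would split.
* Docking energies are pass-through metadata; no scoring or ranking is
  attempted.
* Correlations across protein conformational states (e.g. comparing
  up/down voltage-sensor states) are left to the caller: run the
  workflow per state and compare the summaries.
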
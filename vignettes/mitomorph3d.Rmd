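---
title: "Methods: 3D mitochondrial morphometry with mitomorph3d"
author: "mitomorph3d authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D mitochondrial morphometry with mitomorph3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the quantities it
computes, the numerical choices behind them, the tunable parameters, and
what its synthetic-data tests do and do not demonstrate about real
electron-microscopy data.

## Input model

The raw input is an integer-labeled voxel grid (`labeled_volume`): label
0 is background, every positive label one traced organelle. Serial block
face scanning electron microscopy images transversely to the muscle
fiber at roughly 10 nm pixels and 30 nm section thickness, so the default
voxel size is `(dx, dy, dz) = (10, 10, 30)` nm, grids are stored as
`(x, y, z)` arrays with `z` the section axis, and by default `z` is also
the fiber's longitudinal axis. Both the voxel size and the longitudinal
axis are explicit fields, never inferred.

One label may still contain several spatially disjoint organelles (label
reuse across a large stack), so organelles are the 26-connected
components of each label: diagonal voxel contacts are treated as the same
organelle, mirroring segmentation by a continuous outer membrane.
Components that touch the volume boundary are truncated by the imaged
block and are flagged; `exclude_border = TRUE` removes them from
downstream statistics.

## Surface reconstruction and the complexity index

Surface area and volume come from a closed triangle mesh of each
organelle, extracted by **marching tetrahedra** on the voxel-center
lattice (six tetrahedra per cell sharing a common diagonal, so facets of
neighboring cells agree and the surface is watertight by construction).
Vertices are computed in physical nm, respecting the anisotropic voxel
size.

Contouring the raw 0/1 occupancy produces a faceted staircase whose area
systematically overestimates the true surface — on a voxelized 500 nm
sphere by ~32%. We therefore pre-filter the binary occupancy with a small
Gaussian (`smooth_sigma`, default 1.5 voxels per axis) and contour the
smoothed field at 0.5. The filter is symmetric, so flat interfaces stay
put; the residual bias is a curvature term of order `σ²/r` that shrinks
under grid refinement. Measured against analytic oracles at
`(10, 10, 30)` nm:

| phantom | SA error | V error | MCI error |
|---|---|---|---|
| sphere r = 500 nm | +0.05% | −0.7% | +1.5% |
| sphere r = 250 nm | −1.3% | −2.8% | +1.6% |
| capsule r = 300, L = 2000 nm | −0.2% | −0.5% | +0.5% |
| capsule r = 150, L = 1500 nm | −0.3% | −0.5% | 0.0% |

Setting `smooth_sigma = 0` restores raw-binary contouring; a
`laplacian_passes` option additionally smooths mesh vertices. For objects
so small that the filter would erase them entirely the raw field is
contoured automatically; the resulting contour of an isolated voxel is a
closed polyhedron enclosing roughly half the voxel volume, which is why
organelles under `min_voxels` (default 20) are kept but flagged
unreliable.

Volume is the divergence-theorem signed volume of the mesh, reported
positive regardless of orientation convention; surface area is the sum of
triangle areas. The voxel-count volume (`count · dx·dy·dz`) is retained
as a cross-check column, and rows where mesh and voxel volume disagree by
more than `volume_tolerance` (default 10%) are flagged. MCI uses mesh SA
and mesh V so that numerator and denominator describe the same surface:

\[ \mathrm{MCI} = \frac{SA^3}{16 \pi^2 V^2}, \qquad
   \mathrm{sphericity} = \frac{\pi^{1/3} (6V)^{2/3}}{SA}. \]

MCI is exactly scale-invariant (`MCI(c²SA, c³V) = MCI(SA, V)`) and
bounded below by the spherical value `9/(4π) ≈ 0.7162`; the algebraic
identity `MCI · sphericity³ = 9/(4π)` is asserted in the tests to 1e-12.
The index is deliberately *not* renormalized to 1 for the sphere.

## Branching index

The MBI compares branching across the fiber with branching along it:

- transverse indicator `tbi = myofibrils bridged + 1`;
- longitudinal indicator
  `lbi = 2·sarcomeres + half-sarcomeres + z-bands + 1`;
- `MBI = tbi / lbi`, classified `transverse` (> 1), `equal` (= 1) or
  `longitudinal` (< 1) by comparing the integers `tbi` and `lbi`
  directly, so the three-way split has no floating-point tolerance band.

Annotation mode (counts scored by a human against visible myofibrils and
z-bands) is the faithful mode; CSVs of counts feed the `branching` CLI
subcommand. Geometric mode (`branch_counts_geometric`) is an explicitly
labeled approximation from skeleton extents against a regular lattice
with defaults `myofibril_width = 1000` nm and `sarcomere_length = 2000`
nm: myofibrils bridged is the larger transverse extent over the two
transverse axes in units of the myofibril width (when sides differ the
greater value counts); full sarcomeres are `floor(extent / s)` with one
half-sarcomere if the remainder reaches `s/2`. When z-band plane
positions are supplied, planes crossed beyond the organelle's *home*
plane (nearest its centroid) are counted once each, minus those already
accounted for by counted sarcomeres and half-sarcomeres — each
longitudinal feature counts exactly once; without plane positions z-band
counts are zero and the result carries an `approximate` flag.
"Spanning a sarcomere" is inclusive: a longitudinal extent exactly equal
to the sarcomere length spans it.

## Nanotunnel detection and anatomy

Nanotunnels are thin double-membrane projections, either free-ended or
connecting two mitochondria. The printed literature gives observed
dimensions (external diameters ~26–204 nm, lengths ~65 nm–2 µm) but no
algorithmic criterion, so detection thresholds are explicit parameters
chosen to bracket those ranges: `d_max = 250` nm (maximum external
diameter) and `l_min = 50` nm (minimum length), both configurable.

On a voxel mask the algorithm works on the exact anisotropic Euclidean
distance transform (computed by the lower-envelope parabola method per
axis):

1. **Bodies** are the morphological opening of the mask by a ball of
   radius `d_max/2` — everything that ball can sweep — computed via two
   distance transforms, with one voxel diagonal of slack to absorb the
   discretization rind the opening leaves on curved surfaces.
2. The complement (thin regions) is split into 26-connected components;
   a component attached to at least one body is a candidate.
3. The **centerline** is the geodesic voxel path between the two body
   attachments (anchored at the mouth voxel of maximal clearance), or
   from the single attachment to the geodesically farthest voxel when
   free-ended. Length adds back the gap between each attached terminus
   and the ideal body surface, so it runs body surface to body surface.
4. The **external diameter profile** is twice the distance transform
   along the path. Nodes within `d_max/2` arc length of either end are
   excluded from the min/max (attachment nodes see into the body and
   inflate the local inscribed sphere; free tips taper toward zero), with
   a midpoint fallback for short tunnels.
5. Candidates shorter than `l_min` are dropped; the rest are classified
   `connecting` when two distinct bodies attach, else `free_ended`.

The same logic runs on a `skeleton_graph` with per-node radii (maximal
thin sub-paths, termini attached to thick nodes), which also serves the
annotation workflow where endpoints are supplied rather than detected.

Diameters inherit the discrete distance transform's ±half-voxel-diagonal
uncertainty (±17 nm at default resolution); on dumbbell phantoms the
measured diameter stays within one voxel diagonal and the length within
5% of the constructed truth.

The minimum matrix lumen subtracts `membrane_correction = 24` nm from the
minimal external diameter (2 nm outer membrane + 2 nm inner membrane +
8 nm intermembrane space, on both sides); the constant is configurable so
other membrane models are expressible, and negative estimates clamp to
zero with a flag rather than erroring. Frequencies are reported per 100
mitochondria, and nucleoid passability is the fraction of lumens strictly
wider than `nucleoid_diameter = 110` nm.

## Population analytics

Simple/complex and small/large classes are defined against the pooled
healthy-control population: the 10th and 90th percentiles of MCI and
volume, computed by linear interpolation between order statistics (the
"type 7" rule — pinned because the by-construction test asserts that the
control pool itself classifies exactly 10% simple). Class membership uses
strict inequalities; a value tied with a threshold falls in the middle
class, keeping the control baseline at or below 10%.

Coefficients of variation are reported at three levels, all as SD/mean on
the natural scale: per-cell (across mitochondria of one cell, with the
range across cells), between-cell (CV of cell means within a person), and
between-person (CV of person means). Cells with a single mitochondrion
are excluded with a warning. Distribution shape uses moment skewness
(`g1`) and, by default, *raw* (non-excess) Pearson kurtosis — Gaussian
= 3 — with an `excess` option, since either convention is in use and the
package should be explicit rather than guess. Volume density is the
percentage of a fiber reference volume (conventionally two full
sarcomeres) occupied by mitochondria; a mitochondrial total exceeding the
fiber volume is rejected as a segmentation inconsistency.

## Inference

Group comparisons use the Mann-Whitney rank-sum test; for combined
samples of at most 20 the two-sided p comes from exact enumeration of all
group assignments (valid under ties — the textbook exact distribution is
not), above that from the normal approximation with tie correction.
Class-proportion contrasts (e.g. MBI classes across cohorts) use
Pearson's chi-square without continuity correction.

Variance decomposition fits a linear mixed model with person and
cell-nested-in-person random intercepts by REML (lme4), on the natural
log scale by default because morphological metrics are strongly
right-skewed (the base is irrelevant to SD ratios). With a single cell
per subject the cell component is reported as inestimable rather than
silently dropped. Group labels enter as fixed effects only; random slopes
are out of scope. A balanced-design expected-mean-squares decomposition
serves as an independent oracle in the tests, and parameter recovery is
verified at study scale (8 subjects × 3 cells × 50 mitochondria) against
generating SDs of 0.81 (within-cell), 0.14 (between-cell) and 0.28
(between-person), with the mean estimate over 20 simulation seeds
recovered within 25% per component.

## The multivariate signature

Eight per-individual features (percent simple, complex, small, large;
median MCI; median volume; volume density; nanotunnels per 100) feed a
PLS-DA implemented from scratch with NIPALS: one-hot group response,
columns autoscaled (centered, unit variance — configurable off, since
scaling conventions differ between implementations), deterministic for a
fixed input. Per-component explained X- and Y-variance are reported from
the deflation; the explained-variance accounting is documented here and
is not claimed to match any particular library bit-for-bit. When X
carries no covariance with the response (degenerate labelings) the
algorithm falls back to the leading principal direction, which yields
zero discriminative variance rather than NaNs.

VIP scores use the standard weighting of squared (unit-norm) weights by
per-component explained Y-variance; `mean(VIP²) = 1` exactly, asserted to
1e-10. Prediction projects new rows through the training
centering/scaling and assigns the nearest group centroid in score space.
Cross-validated generalization error on 14 individuals is deliberately
out of scope; the reference PLS-DA implementation in mixOmics is used in
the test suite as an independent cross-check of scores and VIP ranking,
never as the implementation.

## Synthetic data: what it emulates and what it does not

The phantom generator renders implicit solids (spheres, capsules,
dumbbells with nanotunnels, capsule networks) on anisotropic grids with
analytic surface area and volume attached, and builds fiber volumes with
organelles placed at z-band planes in a chosen transverse / equal /
longitudinal mix (defaults 40.4 / 50.6 / 9.1%, the healthy-control
proportions), a chosen nanotunnel rate per 100 (default 2.1), sarcomere
length 2.0 µm, myofibril width 1.0 µm, and at least one background voxel
between organelles so component extraction is unambiguous. A 15 µm fiber
width bounds the layout; requesting more organelles than fit is an error.
Shape dimensions (body radii 180–300 nm, tube 100 × 800 nm, capsule radii
120–200 nm) sit inside the observed ranges.

The cohort generator draws per-mitochondrion volume and MCI from
hierarchical lognormals (person / cell / within-cell components at the
reported log-scale SDs; MCI as a spherical floor plus lognormal excess;
geometric-median volume 0.25 µm³, a typical intermyofibrillar value), and
shifts the disease group's MCI location so a target fraction (default
0.46) of its distribution lies below the control population's theoretical
10th percentile; nanotunnel counts are Poisson at 2.1 vs 38 per 100.
A separate feature-level generator produces per-individual summary
vectors in which *only* chosen features differ between groups, for
signature-recovery experiments.

Passing tests on these phantoms demonstrates that the geometry,
statistics and signature machinery are correct at SBF-SEM voxel
anisotropy and study-scale sample sizes. They do not demonstrate
robustness to segmentation error, membrane-contact ambiguity between
adjacent organelles (touching pairs merge under a continuous-membrane
rule — the generator can produce them, but resolving them is out of
scope), cristae-level structure, or raw-image noise: inputs are assumed
to be correct label masks.

## Problem sizes and determinism

All generators take a mandatory seed and are bit-reproducible; the CLI
writes a manifest (command, merged configuration, input hashes, seed,
version) beside every output, and the simulate→metrics→popstats→signature
chain is bit-stable across reruns. The test suite and the acceptance
script run on deliberately modest problem sizes — phantom spheres up to
r = 500 nm at full 10×10×30 nm resolution, fiber volumes of 10–48
organelles at 20–40 nm pitch, 20-seed variance-recovery and 100-seed
VIP-recovery ensembles — chosen so the whole suite completes in well
under a minute on one CPU while still exercising every code path at
realistic anisotropy.

## Known limitations

- Mesh smoothing introduces a curvature-dependent volume bias (~1–3% for
  the smallest reliably meshed organelles); MCI errors stay within 2% on
  analytic phantoms but grow for objects only a few voxels thick, which
  is why `min_voxels` flags them.
- Nanotunnel diameters are quantized by the section thickness; at 30 nm
  sections a 100 nm tunnel's diameter carries ±1 voxel-diagonal
  uncertainty, and tunnels thinner than one section cannot be resolved.
- Geometric MBI counts are extent-based approximations of a judgment a
  human makes against visible tissue landmarks; annotation mode is the
  faithful path.
- The empty-vs-occupied distinction at threshold values is strict and
  documented, but percentile thresholds from small control pools are
  noisy; the package reports them rather than smoothing them.
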
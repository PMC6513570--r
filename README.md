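# mitomorph3d

Quantitative 3D morphometry of mitochondria segmented from serial block
face scanning electron microscopy (SBF-SEM) volumes of skeletal muscle.

Muscle mitochondria are not a uniform reticulum: they are thousands of
mostly distinct organelles, registered at sarcomere z-bands, whose shapes
range from small spheres to extensively branched tubular networks — and
whose morphology shifts in mitochondrial DNA disease. `mitomorph3d` takes
integer-labeled anisotropic voxel stacks (the output of manual or
automated EM segmentation, ~10×10×30 nm voxels) and computes the
morphometric and population-level quantities needed to characterize such
populations:

- **Per-organelle morphometry** — connected-component extraction
  (26-connectivity, border-touching organelles flagged), watertight
  meshing of each organelle by marching tetrahedra on the anisotropic
  grid, surface area `SA` and volume `V`, and from them the
  **mitochondrial complexity index**

  `MCI = SA³ / (16 π² V²)`

  a dimensionless, strictly scale-invariant 3D analogue of the 2D form
  factor. The sphere attains the isoperimetric minimum `9/(4π) ≈ 0.716`;
  branching and surface elaboration increase MCI without bound. Sphericity
  `π^(1/3) (6V)^(2/3) / SA` is computed alongside
  (`MCI · sphericity³ = 9/(4π)` identically).
- **Branching anisotropy (MBI)** — transverse branching indicator
  (myofibrils bridged + 1) over longitudinal indicator
  (2·sarcomeres + half-sarcomeres + z-bands + 1), with a three-way
  transverse / equal / longitudinal classification in exact integer
  arithmetic, from annotation counts or approximately from skeleton
  geometry.
- **Nanotunnels** — detection of thin projections (free-ended or
  connecting two mitochondrial bodies) on the distance transform, with
  centerline length, external diameter extremes, and the estimated matrix
  lumen (`d_ext_min − 24 nm`, two membranes plus intermembrane space per
  side); frequencies per 100 mitochondria and the fraction of lumens
  passable by a ~110 nm mtDNA nucleoid.
- **Population analytics** — simple/complex (MCI) and small/large
  (volume) classes against the 10th/90th percentiles of the pooled
  control population; coefficients of variation within cells, between
  cells and between persons; volume density over two sarcomeres;
  skewness/kurtosis and cumulative distributions.
- **Inference** — Mann-Whitney tests (exact enumeration for small
  samples), chi-square tests on class proportions, and nested
  random-intercept variance components (person / cell-within-person /
  residual, REML on the log scale).
- **Disease signature** — a from-scratch NIPALS PLS-DA over eight
  per-individual features with variable importance in projection (VIP)
  scores (`mean(VIP²) = 1` by construction).
- **Synthetic phantoms** — voxelized spheres, capsules, dumbbells and
  whole sarcomere-registered fiber volumes with analytic ground truth,
  plus hierarchical cohort generators, so every result above is testable
  without any imaging data.

## Worked example

A dumbbell phantom — two 300 nm-radius bodies joined by a 100 nm × 800 nm
nanotunnel — rendered at SBF-SEM resolution and pushed through the
pipeline:

```r
library(mitomorph3d)

vol <- voxelize(shape_spec("nanotunnel_dumbbell", r_body = 300,
                           tube_length = 800, tube_diameter = 100,
                           axis = "x"), voxel_size = c(10, 10, 30))
vol
#> <labeled_volume> 206 x 66 x 26 voxels @ (10, 10, 30) nm, 1 label(s)
#>   longitudinal axis: z

compute_morphometrics(vol)[, c("volume_um3", "sa_um2", "mci", "sphericity")]
#>   volume_um3 sa_um2   mci sphericity
#> 1      0.227  2.451 1.812      0.734

detect_nanotunnels(vol)[, c("length_nm", "d_ext_min_nm", "lumen_min_nm",
                            "end_status")]
#>   length_nm d_ext_min_nm lumen_min_nm end_status
#> 1       800         72.1         48.1 connecting
```

The two-lobed shape scores MCI 1.81 — 2.5× the spherical floor — and the
tunnel is recovered at its true 800 nm length with its diameter within
one voxel diagonal of truth. A plain voxelized 500 nm sphere, for
comparison, scores MCI 0.726 against the analytic floor 0.716 and
sphericity 0.996.

The same steps run from a shell:

```sh
inst/cli/mitomorph3d simulate --preset control --seed 7 --out stack.tif --truth truth.csv
inst/cli/mitomorph3d metrics --volume stack.tif --voxel 20,20,40 --out metrics.csv
inst/cli/mitomorph3d nanotunnels --volume stack.tif --voxel 20,20,40 --out nt.csv
```

Every CLI run writes a JSON manifest (command, merged config, input
hashes, seed, version) next to its output.

## Documentation

The methods vignette (`vignettes/mitomorph3d.Rmd`) describes the model
and its assumptions, the meshing and detection algorithms, all tunable
parameters with units and defaults, what the synthetic generators do and
do not emulate, and known limitations.
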
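---
title: "Lesion frequency mapping with Monte-Carlo cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion frequency mapping with Monte-Carlo cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmap)
```

## Overview

`lesionmap` analyzes the spatial distribution of brain metastases from
binary lesion masks that have been co-registered to a common standard
space. The chain is:

1. build a brain parenchymal mask from gray- and white-matter probability
   maps;
2. reduce each lesion to a single center voxel and compute per-lesion
   metrics (depth, gray-matter density, volumes);
3. aggregate each group's centers into a tumor frequency map with a
   spherical kernel;
4. calibrate voxel-wise and cluster-size thresholds against a uniform
   random null by Monte-Carlo simulation and report significant clusters;
5. compare lesion features between groups with rank-based tests.

Real patient imaging is not distributed with the package. Instead, a
synthetic phantom and cohort generator with known ground truth support
end-to-end validation: every stage can be checked against the parameters
that generated the data.

## Parenchymal mask

The mask is `gm + wm >= 0.1` (inclusive threshold), followed by a
morphological closing with a 3 mm ball and a hole fill. Closing is
implemented as Minkowski dilation then erosion with the same structuring
element; the result is constrained to contain the raw thresholded mask, so
closing can only add voxels. Hole filling flood-fills the background from
the volume border under 6-connectivity and declares every unreached
background voxel interior. This turns ventricles and other enclosed CSF
spaces into mask foreground, which is deliberate: the null model relocates
tumor centers anywhere inside the brain outline.

## Lesion geometry

All distance computations use an exact Euclidean distance transform
(separable lower-envelope algorithm) in world millimeters, so anisotropic
voxels are handled exactly. The convention is that a foreground voxel's
value is the distance to the nearest *background voxel center*; a voxel on
the mask surface therefore has distance one voxel spacing, not zero.

- **Tumor center**: the voxel of the lesion mask with maximal distance to
  the lesion background — the deepest interior voxel. Ties are broken by
  the lexicographically smallest (i, j, k) index, which makes the reduction
  deterministic.
- **Depth**: the value of the parenchymal distance transform at the tumor
  center; centers outside the mask get depth 0 with a warning.
- **Gray-matter density (GMD)**: the gray-matter probability at the center
  voxel, summarized across lesions by a 10-bin histogram on [0, 1] with
  left-closed bins.
- **Volumes**: voxel counts times the voxel volume from the affine
  determinant; the edema/tumor ratio is the edema shell volume over the
  tumor volume (a flag switches to the convention that includes the tumor
  in the numerator).

## Frequency maps

For a group with `n` tumor centers, the frequency map assigns each voxel
the fraction of centers whose world-space distance to the voxel center is
at most the kernel radius (20 mm by default; closed-ball comparison). The
map times `n` is an integer count by construction. Maps are computed by
stamping a precomputed sphere offset template at each center, with a fast
interior path when the sphere is fully inside the grid.

## Monte-Carlo null calibration

The null hypothesis is that tumor centers fall uniformly at random inside
the parenchymal mask, independently of each other. Calibration has two
stages with **independent RNG streams** derived from one master seed (a
third stream serves held-out checks):

1. **Voxel thresholds.** Simulate `n_voxel_sims` null maps with the
   observed group's tumor count; at every voxel take the empirical
   `1 - voxel_p` quantile of its null values. Only per-voxel count
   histograms are kept (counts live in `0..n`), never the maps, so memory
   is independent of the simulation count. The quantile uses interpolated
   order statistics (`h = n p + 0.5`, R's type 5, the Matlab convention); a
   conservative ceiling-rank option is available. Observed maps are
   compared by *strict* exceedance.
2. **Cluster-size threshold.** Simulate `n_cluster_sims` fresh null maps,
   apply the fitted thresholds, label suprathreshold components
   (26-connectivity by default) and pool their sizes. Under the default
   `expected_count` rule the threshold is the smallest integer `T` such
   that oversize clusters occur at most `cluster_p` times per map on
   average — the "5 in every 100 images" reading of p = 0.05. A stricter
   `max_cluster` rule (FWER-style, based on per-map maxima) is available;
   the two differ when maps contain several oversize clusters.

Observed clusters larger than `T` get an add-one rank p-value,
`(1 + #null >= size) / (1 + n_sims)`, which can never be exactly zero. Each
cluster is reported with its size and the world coordinate of its
peak-frequency voxel (lexicographic tie-break). Threshold maps and cluster
nulls carry provenance (mask fingerprint, tumor count, radius, seed) and
refuse to be combined across mismatched inputs.

Simulation is chunked so that center matrices never grow with the total
simulation count; because uniform draws with replacement consume the RNG
stream sequentially, chunked and monolithic runs are bit-identical.

## Synthetic phantom and cohorts

The phantom is an ellipsoidal brain: gray-matter probability rises
logistically from the white-matter core to the cortex, white matter is the
complement up to a fixed tissue total, and an optional ellipsoidal
ventricle is pure CSF. A thin band of voxels at the shell/core interface is
set to gray-matter probability exactly 0.6 — a discrete stand-in for the
gray/white junction. This exact value is a design choice: junction-placed
cohorts then have a GMD histogram whose modal bin provably contains 0.6,
so junction recovery can be asserted without tolerance tuning. The outer
surface is a hard cutoff, so thresholding at 0.1 recovers the true mask
exactly.

Cohorts draw lesions as digital balls (log-normal radii, clipped) with
concentric edema shells, grouped by patient and mutation group. Three
placement models cover the scientifically interesting cases: `uniform`
(matches the null), `junction` (centers on the junction band), and
`hotspot_mixture` (a fraction of centers drawn from an isotropic Gaussian
around a planted hotspot). Ground truth (true centers, radii, depths, GMD,
hotspot origin) is recorded per lesion.

## Reproducibility

All stochastic stages are driven by explicit seeds. `run_pipeline()`
writes a manifest (seeds, parameters, input fingerprints) next to its
outputs; re-running with the same inputs and configuration reproduces
bit-identical metrics, thresholds and cluster reports.

Default problem sizes in the package's own analysis scripts (48^3 grid,
2 mm voxels, 2,000 voxel-threshold and 5,000 cluster-calibration
simulations) are chosen so the whole workflow runs in seconds on one CPU;
they are package defaults for demonstration, and all counts scale up
through `null_config()`.

## Limitations

- The null model treats tumor centers as independent; the optional
  `patient_block` mode relocates each patient's centers rigidly as a
  partial account of within-patient clustering, but no inter-center
  interaction model is provided.
- The phantom is geometric, not anatomical: no atlas labels are attached
  to cluster coordinates.
- The expected-count calibration controls the average number of oversize
  clusters per map, not the family-wise error rate; use `max_cluster` when
  FWER control is wanted.
- Empirical quantiles at `voxel_p = 0.001` need on the order of thousands
  of simulations per voxel; the package warns when `n_voxel_sims` is below
  `1 / voxel_p`.
```{r}
sessionInfo()
```
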
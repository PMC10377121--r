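# lesionmap

Spatial-distribution analysis of brain metastases from co-registered
lesion masks: tumor frequency maps, Monte-Carlo-calibrated cluster
inference, and rank-based group comparisons — plus a synthetic phantom and
cohort generator with known ground truth.

## What it does

Given binary tumor (and optional edema) masks in a common standard space
and gray/white-matter probability maps:

1. **Parenchymal mask** — threshold `gm + wm` at 0.1, morphological
   closing, hole filling (`build_parenchyma_mask`).
2. **Lesion geometry** — exact 3D Euclidean distance transforms locate
   each lesion's deepest voxel (its center) and its depth below the brain
   surface; per-lesion metrics include gray-matter density at the center,
   tumor/edema volumes and their ratio (`compute_lesion_metrics`).
3. **Frequency maps** — per group, each voxel's value is the fraction of
   tumors whose center lies within 20 mm (`build_frequency_map`).
4. **Null inference** — per-voxel 1−p quantile thresholds and a
   cluster-size threshold are calibrated against uniformly random center
   placements in the mask; surviving clusters get Monte-Carlo p-values
   (`estimate_voxel_thresholds`, `calibrate_cluster_threshold`,
   `find_significant_clusters`).
5. **Group statistics** — Kruskal–Wallis (with ANOVA alongside) and
   pairwise comparisons of lesion features (`compare_groups`).

`run_pipeline()` chains all stages and writes CSV/NIfTI outputs plus a
reproducibility manifest. Because clinical imaging cannot be shipped, the
package includes a deterministic ellipsoidal brain phantom
(`make_phantom`) and a lesion-cohort simulator (`sample_cohort`) with
uniform, gray/white-junction, and planted-hotspot placement models, so the
entire chain is testable against known ground truth.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
synthetic three-group cohort (EGFR: hotspot-concentrated, ALK: junction,
KRAS: uniform; 10 patients per group, 5–30 tumors each on a 48³ grid at
2 mm). From the repository root, with the package installed:

```sh
Rscript analysis/01_simulate.R        # phantom + cohort -> results/cohort/
Rscript analysis/02_lesion_metrics.R  # mask + per-lesion metrics
Rscript analysis/03_frequency_maps.R  # per-group frequency + difference maps
Rscript analysis/04_null_inference.R  # thresholds + significant clusters
Rscript analysis/05_group_statistics.R
```

Output of one complete run (about a minute total on one CPU):

```
wrote 538 lesions (EGFR: 158, ALK: 191, KRAS: 189) to results/cohort
parenchyma: 33184 voxels; 538 lesions; GMD peak bin center 0.65
ALK: 191 tumors, peak frequency 0.246
EGFR: 158 tumors, peak frequency 0.791
KRAS: 189 tumors, peak frequency 0.206
ALK: cluster-size threshold 153 voxels; 1 significant cluster(s)
EGFR: cluster-size threshold 146 voxels; 1 significant cluster(s)
KRAS: cluster-size threshold 142 voxels; 0 significant cluster(s)
 group cluster_id size_voxels rep_x_mm rep_y_mm rep_z_mm    p_value
   ALK          1        1058        7       -1       15 0.00039992
  EGFR          1        6293       21      -13        3 0.00019996
```

The generator planted the EGFR hotspot at (20, −15, 5) mm; the detected
EGFR cluster peaks at (21, −13, 3) mm with p ≈ 2 × 10⁻⁴. The junction-placed
ALK group also concentrates spatially (the junction band is a thin shell)
and yields a cluster, while the uniform KRAS group — which matches the
null — yields none. The GMD histogram peaks in the bin containing the
configured junction value 0.6. Among the lesion features only depth
separates the groups (Kruskal–Wallis H = 20.0, p ≈ 4.5 × 10⁻⁵): junction
lesions sit at a fixed shallow shell, uniform lesions spread over all
depths.

## Repository layout

- `R/`, `src/` — the package (all computation; C++ for the distance
  transform, sphere stamping, histograms and connected components).
- `analysis/` — numbered workflow drivers writing `results/`.
- `scripts/acceptance.R` — calibration measurement, see above.
- `tests/testthat/` — oracle-based test suite.
- `vignettes/lesion-frequency-mapping.Rmd` — methods notes: conventions,
  calibration rules, generator design, limitations.
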
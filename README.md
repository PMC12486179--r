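# cysthead

Quantitative analysis of subchondral cystic lesions in the femoral head
from volumetric micro-CT, for researchers studying osteoarthritis (OA)
and osteonecrosis of the femoral head (ONFH). The package implements, as
one reproducible pipeline:

* **Cyst extraction** — bone binarized in a global 8-bit window
  ([90, 255]); the head envelope ("total region") built by morphological
  closing + cavity filling; voids derived by set difference; voids whose
  largest inscribed sphere is below 1 mm removed by erosion with a
  Euclidean ball of radius `d_min/2` (in 0.5 mm increments) followed by a
  restoring dilation — either geodesic reconstruction (whole components)
  or increment-limited (compact voids only); labelled cysts summarized as
  Cyst.N, Cyst.V, CystV.Ave, CystV.Min, CystV.Max (mm³).
* **Six-region / three-pillar segmentation** — a reference plane through
  the head, fovea and neck centres splits anterior/posterior; two planes
  parallel to the main trabeculae direction (MTD) and perpendicular to
  the reference plane split the head width 30 % / 40 % / 30 % into
  lateral, central and medial pillars (regions I–VI). Each cyst is
  assigned to the region containing its largest voxel share.
* **Peri-cyst trabecular morphometry** on the Cys-Tb shell (0.5 mm
  outward from the cyst surface): BV/TV (%), BS/BV (1/mm), Tb.Th and
  Tb.Sp (µm, sphere-fitting local thickness), Tb.N = 1/(Tb.Th+Tb.Sp)
  (1/mm), SMI (6·V·S′/S², parallel-surface expansion), DA (longest /
  shortest principal mean-intercept-length axis), Conn.D = (1−χ)/TV
  (1/mm³, exact cubical-complex Euler characteristic).
* **2D histomorphometry** on labelled sections: O.Th, OV/BV, OS/BS,
  OS/BV, ES/BS, ES/BV, ES/TV, plus Weidner microvessel density
  (isolated endothelial clusters per high-power field).
* **Two-group statistics** — Kolmogorov–Smirnov (Lilliefors) normality
  routing into pooled t-test or asymptotic Mann–Whitney U; uncorrected
  Pearson chi-squared (Yates / Fisher variants) for categorical rows; a
  baseline-characteristics table builder with `mean (SD)` / `n (%)`
  formatting.
* **A synthetic femoral-head phantom** (band-pass random-field trabecular
  texture, cortical shell, spherical cysts with optional sclerotic rim,
  blur + noise) with full ground truth, so the whole chain is testable
  without scan data.

All tabular results are tibbles; volumes are lightweight `voxel_volume`
arrays with physical spacing; the compute-heavy voxel primitives
(distance transforms, labelling, local thickness, MIL ray casting) are
in C++.

## Worked example

The packaged demo configuration generates a 10 mm-radius phantom head at
0.25 mm voxels with three cysts (3, 2 and 1.5 mm diameter) and runs every
stage:

```r
library(cysthead)
res <- run_pipeline(pipeline_demo_config(), output_dir = tempfile())
res$records[, c("id", "volume_mm3", "diameter_mm", "region", "pillar", "hemisphere")]
#>   id volume_mm3 diameter_mm region  pillar hemisphere
#> 1  1       1.92        1.33      V central  posterior
#> 2  2       4.02        1.81      V central   posterior
#> 3  3      15.31        2.79     II central   anterior
res$summary
#>   cyst_n cyst_v cystv_ave cystv_min cystv_max
#> 1      3  21.25     7.083     1.922     15.31
```

All three cysts are recovered; the volumes sit within 10 % of the
analytic sphere volumes (14.14, 4.19, 1.77 mm³ — the small excesses are
the blurred, noisy binarization, exactly as on a real scan), and each is
localized to its pillar and hemisphere. `res$morphometry` holds the
8-parameter Cys-Tb panel per cyst; on this phantom the shells are
dominated by the sclerotic rim, so BV/TV is high (70–87 %) and the SMI of
the nearly solid, concave shell goes negative, as that index does on
enclosed surfaces.

The statistics module reproduces clinical baseline tables; for example, a
sex split of 33/12 vs 78/27 under the default uncorrected chi-squared:

```r
tidy(compare_categorical(matrix(c(33, 78, 12, 27), 2)))
#>   test  statistic     p significant
#> 1 chi2     0.0149 0.903 FALSE
```

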
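# pollendiv

Calibrating pollen-based plant diversity across spatial scales.

Fossil pollen is the main proxy for past plant diversity, but a pollen
sample integrates the surrounding vegetation over an unknown area. Modern
calibration studies pair pollen samples (moss polsters) with exhaustive
vegetation surveys out to 1 km around each sampling point, in regions and
habitats with contrasting diversity, and ask at which radius pollen
diversity best predicts plant diversity — the *source area of pollen
diversity*. `pollendiv` implements that calibration chain as a tested R
package:

* **Rarefaction** of pollen counts to a common grain sum by multivariate
  hypergeometric subsampling (default 943 grains, 100 repeats, median
  taxon count), with the exact expectation
  `E[S] = Σ_t (1 − C(N−c_t, d)/C(N, d))` available as an oracle.
* **Pollen-productivity correction**: counts divided by relative PPEs
  (taxa without an estimate pass through, flagged), then multinomially
  resampled to 520 grains.
* **Beta diversity as total variance**: for a presence–absence table with
  (square-root-transformed) Jaccard dissimilarities,
  `BD_Total = SS_total/(n−1) ∈ [0,1]` via Gower centering of `−D²/2`, with
  per-site local contributions `LCBD_i = SS_i/SS_total` and
  within-species permutation p-values. The identity
  `SS_total = (1/n) Σ_{i<j} D_ij²` is the built-in cross-check.
* **Radius-scanning regression**: at each radius of a 0.5–1000 m grid,
  OLS of pollen diversity on plant diversity (richness, BD_Total, or
  LCBD); the source area is the radius with maximal adjusted R², ties
  broken inward.
* **A synthetic landscape generator** (concentric habitat mosaics,
  species pools, dispersal kernels, PPEs, long-distance background,
  canopy interception) with closed-form ground truth for the effective
  source radius, so the whole pipeline is testable without field data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a field-study campaign (two regions, 21 + 39 sites, forest/open
subsets, 2000 grains per sample) and writes plain-CSV fixtures; later
stages only read files.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_rarefy.R
```

```
Mean rarefied pollen richness (943 grains, median of 100 draws):
region_poor_complete   region_poor_forest     region_poor_open
                50.0                 41.9                 57.3
region_rich_complete   region_rich_forest     region_rich_open
                89.3                 79.9                 98.1
```

Forest sites sit below open sites within each region (tree pollen
dominates their rain) and the species-poor region sits below the
species-rich one — the rank order the calibration is built on.

```sh
Rscript analysis/04_beta_diversity.R
```

```
              dataset n_sites ss_total bd_total
 region_poor_complete      21     5.02    0.251
   region_poor_forest      10     1.93    0.215
     region_poor_open      11     1.96    0.196
 region_rich_complete      39     9.77    0.257
   region_rich_forest      19     3.86    0.214
     region_rich_open      20     3.06    0.161
```

Because BD_Total is bounded in [0, 1], datasets of different sizes are
comparable: each complete dataset exceeds both of its habitat subsets —
mixing forest and open sites adds compositional variance.

```sh
Rscript analysis/05_source_area.R
```

```
BD_Total scan peak: adj R^2 = 0.96 at 350 m (p = 0.00044)
Survey completeness against the regional reference pools:
  species-poor region: 54.1 %
  species-rich region: 53.7 %
```

`analysis/03_ppe_adjust.R` adds the productivity-corrected richness, and
the same stages are available programmatically through `run_pipeline()`.

## Layout

```
R/                  package code (I/O, rarefaction, PPE adjustment,
                    beta diversity, spatial scaling, generator, pipeline)
analysis/           numbered workflow scripts (write under results/)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, choices, limitations)
```
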
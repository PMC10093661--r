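# budscan

Automated tumor-budding quantification for cytokeratin (pan-CK) IHC slides.

Tumor budding — single tumor cells or clusters of up to four cells at or near
the invasive front — is a prognostic biomarker in colorectal carcinoma.
Consensus scoring (ITBCC 2016) counts buds inside a circular "hotspot" of
radius 0.5 mm (area 0.785 mm²) placed on the densest budding region, and
converts the count to a three-tier score: Bd1 (0–4 buds), Bd2 (5–9), Bd3
(≥ 10). `budscan` implements the desk-scale computational core of an
automated version of this workflow for users who already have per-slide bud
detections (from a CNN, a classical detector, or manual annotation):

- **Density mapping** — for every raster cell, the exact number of buds
  inside the 0.5 mm disk centered there:
  `D(p) = #{ b : ‖b − p‖ ≤ r }`, with `r = 500 µm`.
- **Hotspot selection** — greedy argmax with overlap suppression: repeatedly
  take the cell with the highest in-disk count, zero all cells within one
  radius, until 10 fields are found. Successive centers are therefore ≥ r
  apart.
- **ITBCC scoring** — the rank-1 hotspot count mapped onto Bd1/Bd2/Bd3, plus
  median / fixed-cutoff dichotomization for cohort analyses.
- **Spatial heterogeneity** — Shannon entropy `H = −Σ pⱼ log pⱼ` of the
  density map (`pⱼ` = cell j's share of the total count mass), with
  `H / log K` as a normalized version.
- **Stain tools** — H-DAB color deconvolution (Ruifrok–Johnston basis),
  DAB-positive masking with 8-connected components, and a classical
  mask-based candidate detector.
- **Pseudo-labeling** — teacher–student dataset construction: strict
  likelihood filter (> 0.80), DAB-mask rejection, manual-precedence merging
  with certainty weights (manual 1.0, pseudo 0.80).
- **Evaluation** — sensitivity against sparse references, paired Pearson
  count comparison, top-3/top-10 hotspot agreement via the circle Dice
  coefficient (match at Dice ≥ 0.7).
- **Synthetic slides** — seeded generator of clustered bud patterns with a
  brute-force planted densest disk, teacher likelihood noise, and rendered
  DAB tiles, so the whole pipeline is testable without any WSI data.

## Worked example

```r
library(budscan)

sl  <- simulate_slide(simulation_config(seed = 11))   # 10 x 10 mm synthetic slide
fit <- tb_budding(sl$true_buds, geometry = sl$geometry)
fit
#> Tumor budding quantification
#>   buds counted: 119; hotspots extracted: 10 (radius 500 um)
#>   hotspot count: 29  ->  ITBCC tier Bd3
#>   density entropy: 13.0434 (normalized 0.9146)

match_hotspots(sl$planted_hotspot, fit$hotspots)
#> hotspot match: rank 1 (dice 1.000) [top 3]
```

The slide carries 119 buds, most of them in one planted cluster. The rank-1
hotspot holds 29 buds, so the slide scores Bd3 (high budding); the automatic
field coincides exactly with the ground-truth densest disk (Dice 1.0). The
density entropy of 13.04 (normalized 0.91) reflects a mostly diffuse
background with one concentrated cluster. `summary(fit)` lists all ten
ranked hotspots; `plot(fit)` draws the density heatmap with the field
circles; `coef(fit)` returns the per-slide biomarkers as a named vector
ready for a cohort table.

A thin command-line front end over the same functions is installed at
`inst/cli/budscan.R` (subcommands `simulate`, `candidates`, `density`,
`hotspots`, `score`, `entropy`, `pseudolabel`, `evaluate`).

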
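---
title: "Quantifying tumor budding from whole-slide bud detections"
author: "budscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor budding from whole-slide bud detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budscan)
```

## The measurement problem

Tumor budding in colorectal carcinoma is scored by finding the region of a
slide with the highest density of buds — single tumor cells or clusters of up
to four cells — and counting buds inside a circular field of radius 0.5 mm
(0.785 mm²) placed there. The count maps onto a three-tier scale: Bd1 for
0–4 buds, Bd2 for 5–9, Bd3 for 10 or more. Done visually, both the field
placement and the count are subjective; done computationally from a list of
detected bud coordinates, both become deterministic, and the whole slide can
be scanned rather than a pre-selected region.

`budscan` starts where a detector (a CNN, a stain-based classical detector,
or a human annotator) stops: its inputs are point sets in slide-frame
micrometers, optionally with class likelihoods and labels. Everything
downstream of detection — density mapping, hotspot extraction, scoring,
heterogeneity biomarkers, pseudo-label dataset construction, and detector
evaluation — is implemented and validated here.

## Density mapping and hotspot extraction

The density map assigns to every raster cell the number of buds within
radius $r$ of the cell center:

$$D(p) \;=\; \#\{\, b \in B : \lVert b - p \rVert \le r \,\},$$

with $r = 500\ \mu m$ by default. Two conventions matter:

* **Closed disks.** A bud exactly at distance $r$ counts as inside. The
  choice is arbitrary at measure zero but must be fixed for determinism;
  membership is tested on squared distances, so no square root is taken.
* **Exact point geometry.** Detection coordinates are never binned to the
  raster; the map depends only on true distances from cell centers. A map at
  8 µm spacing is therefore not an approximation of a finer map — it is the
  same function sampled more coarsely.

The raster spacing defaults to 8 µm. Scanning at full scan resolution
(~0.24 µm) would cost three orders of magnitude more cells and buy nothing:
the only quantity read off the map is the argmax location, whose
discretization error is at most half a cell (4 µm), negligible against the
500 µm field radius. The raster covers the detections' bounding box padded
by one radius (or an explicit `slide_geometry`), so the densest disk can
never be clipped by the extent.

Hotspots are extracted greedily: take the cell with the highest count as the
rank-1 center, zero every cell whose center lies within one radius of it,
and repeat until $k = 10$ fields are found or the map is exhausted (fewer
fields, with a warning). Zeroing a full radius guarantees successive centers
are at least $r$ apart; two neighbouring fields can then overlap by at most
the lens area at center distance $r$, which is ≈ 39.1 % of one field
(Dice ≈ 0.391). Ties at the argmax are broken by the smallest row-major cell
index — deterministic across platforms. An alternative
remove-points-and-recount mode (`recount = TRUE`) deletes the buds of each
selected field and recomputes the map; it is provided for sensitivity
analyses and is off by default, since the zeroing semantics is the canonical
definition of the procedure.

Automatic fields are compared with a manually placed field through the
analytic Dice coefficient of two disks (circular-lens intersection area); a
Dice of at least 0.7 counts as a match, which for equal radii corresponds to
a center distance of ≈ 0.476 r. Agreement over a cohort is summarized as the
fraction of slides whose manual field matches an automatic field of rank
≤ 3, rank ≤ 10, or none.

## Scoring and heterogeneity

The rank-1 count is converted to Bd1/Bd2/Bd3. For cohort analyses,
continuous biomarkers (automated counts, entropies) are dichotomized at the
cohort median with a strict `>` (ties to low — the conservative convention;
configurable), or at a fixed threshold.

Spatial spread is quantified by Shannon entropy over the density map's
cells: with $p_j$ the cell's share of the total count mass,
$H = -\sum_j p_j \log p_j$ (natural log by default; base configurable), and
$H/\log K$ as a normalized version over $K$ cells. The distribution is taken
over the raw count grid, not the per-slide normalized grid (which does not
sum to one). A slide with zero counted buds has no distribution; this is
reported as an error state distinct from $H = 0$, which means "all mass in
one cell". Note that $H$ depends on the raster spacing through $K$, so
entropies should only be compared across slides mapped at the same spacing
— the per-slide CSV produced by the evaluation tools records the spacing for
this reason.

## Stain deconvolution and the DAB mask

RGB tiles are converted to optical density, $OD_c = -\log_{10}((I_c + 1)/255)$
(the +1 guards $\log 0$), and unmixed through the inverse of a stain matrix
whose rows are unit OD vectors for hematoxylin and DAB (published
Ruifrok–Johnston values), with the residual direction as their normalized
cross product. Negative concentrations are clipped at zero. A red CD8
chromogen, when present, lands in the residual channel and is ignored.

The DAB-positive mask thresholds the DAB concentration at 0.15 OD, applies a
morphological opening with a 1-pixel-radius disk, labels 8-connected
components, and discards components below 30 µm². None of these three values
is canonical — they are exposed as arguments and chosen to recover rendered
synthetic blobs robustly over a ten-fold DAB intensity range; on real
material they are per-lab tuning parameters. Component labeling is
implemented in-package because the available image library labels
4-connected regions, and diagonal adjacency must fuse blobs here.

## Pseudo-label dataset construction

A teacher detector applied to a whole slide yields dense candidates with
likelihoods. The training set for a student is built by three filters whose
semantics are strict and order-independent:

1. **Likelihood**: keep candidates with likelihood strictly greater than
   0.80 — a candidate at exactly 0.80 is rejected.
2. **DAB gate**: reject candidates not on a DAB-positive mask pixel
   (tolerance 0 µm by default; a configurable tolerance accepts candidates
   within that distance of a positive pixel center).
3. **Manual precedence**: manual annotations are always retained at
   certainty 1.0; retained pseudo-labels get certainty 0.80; a pseudo-label
   within 15 µm of a manual annotation (about one cell diameter) is dropped
   so no object is supervised twice.

The certainty field is the hand-off contract to any training framework that
weights losses; training itself is out of scope. The likelihood threshold
and the pseudo certainty are both 0.80 by default but are independent
configuration fields.

## Detector evaluation

With sparse references (not every bud on the slide is annotated), false
positives are unidentifiable, so the detector is scored by sensitivity
alone: the fraction of reference buds with a predicted detection within
25 µm, under greedy nearest-first one-to-one matching (ties broken by index)
so one prediction cannot cover two reference buds. The 25 µm default is
roughly two cell diameters; sensitivity is monotone in it, and the reported
radius always accompanies the score. Paired manual/automatic counts from the
same field are compared by Pearson correlation and by the mean count ratio.

## The synthetic-slide generator

Real validation data for this pipeline are private WSIs; the generator
replaces them with point patterns whose ground truth is known exactly. It
emulates:

* a homogeneous Poisson background of buds (default 1 /mm² over a
  10 × 10 mm tissue — a plausibly budding-rich section);
* one dominant Gaussian cluster (25 buds, sd 50 µm) whose planted densest
  disk — computed by an exhaustive compiled scan over all grid centers,
  a different algorithm and code path from the production density map — is
  the recovery target;
* non-bud distractors (1 /mm²) and sparse manual annotations (10 % of
  objects), mirroring sparse expert labeling;
* teacher likelihoods from Beta(8, 2) at true buds and Beta(2, 8) at
  Poisson false positives (0.5 /mm²), so the 0.80 cut keeps most but not
  all true buds and admits almost no noise — the filter is exercised
  meaningfully rather than trivially;
* rendered DAB imagery via the Beer–Lambert forward model
  $I = 255 \cdot 10^{-M^\top c}$ with the same stain basis the
  deconvolution inverts, white background, bounded uniform pixel noise.

What it does **not** emulate: tissue texture, stain variation across labs,
clustered false positives near ruptured glands, scanner artifacts, or the
invasive-front geometry that guides human field placement. Passing the
synthetic suites therefore demonstrates the correctness of the computational
procedure, not detector performance on clinical material.

All draws derive from one integer seed; equal seeds give byte-identical
serialized outputs.

## Validation strategy and problem sizes

The test suite checks each stage against an independent reference
implementation rather than against itself:

* density maps against a per-pixel brute-force scan (exact integer equality
  on 50 random instances, grids up to 400 × 400, up to 500 points);
* rank-1 hotspots against the exhaustive densest-disk scan, and planted
  hotspot recovery at Dice ≥ 0.7 in at least 95 of 100 seeded default-config
  simulations;
* analytic circle Dice against a 1 µm rasterized-mask computation
  (within 0.005);
* deconvolution against the Beer–Lambert forward renderer (coefficients
  within 0.02, blob counts exact over a 10× intensity range);
* metric definitions against hand-computed fixtures.

These sizes keep the default suite under a minute of compute while leaving
every assertion exact or tightly toleranced.

## Known limitations

* Hotspot disks may overhang the raster edge and simply count fewer cells;
  no tissue-boundary correction is applied.
* Entropy values depend on raster spacing; compare only at equal spacing.
* The DAB mask thresholds are synthetic-calibrated defaults, not clinically
  validated constants.
* The stand-in mask-based candidate detector is a classical size heuristic;
  it exists so the pipeline runs end-to-end without a learned model, not as
  a substitute for one.
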
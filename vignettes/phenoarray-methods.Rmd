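---
title: "phenoarray: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoarray: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenoarray)
```

This vignette is the package's own account of the science it implements:
the measurement model, the synthetic world used to test it, the tunable
parameters, and the design decisions taken where the underlying assay
description left the choice open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A phenotypic cell microarray couples reverse transfection to high-content
imaging. Spots of siRNA or microRNA mimic (plus lipid reagent, a
fluorescent tracer RNA for spot visualization, sucrose and gelatin) are
printed at ~300 µm diameter on a coated slide; a cell monolayer seeded on
top is transfected locally over each spot. After ~48 h the slide is fixed,
immunostained for the phenotype protein and counterstained for DNA, then
imaged in three channels (tracer ≈ 560 nm, phenotype ≈ 488 nm, nuclei
≈ 635 nm).

The pipeline mirrors that assay stage by stage:

1. **Spot extraction** (`detect_spots`): threshold the tracer channel,
   label connected components, fill holes, keep components whose
   equivalent diameter $2\sqrt{A/\pi}\cdot s$ ($A$ = pixel area, $s$ =
   µm/pixel) lies in a window around the nominal 300 µm.
2. **Grid registration** (`register_to_layout`): estimate a global
   translation (median offset to nearest expected centre), then match
   detections to layout spots one-to-one, greedily nearest-first.
3. **Cell identification** (`segment_nuclei`): Gaussian smoothing, Otsu
   threshold, hole filling, exact Euclidean distance transform, and a
   marker-based watershed that splits touching nuclei; an area filter
   removes debris and unresolvable clumps.
4. **Per-cell intensity** (`measure_phenotype`): the mean phenotype
   intensity per pixel over the nucleus mask dilated by 3 µm, with
   dilated regions of neighbouring cells kept disjoint by nearest-label
   assignment.
5. **Classification** (`classify_expressing`): a cell *expresses* the
   phenotype when its per-cell intensity exceeds a threshold (below).
6. **Scoring** (`assign_cells_to_spots`, `percent_expressing`,
   `normalize_to_control`, `knockdown_test`): cells are associated to
   the registered nominal spot disc; each spot yields
   $P = 100\,n_{\mathrm{expr}}/n_{\mathrm{cells}}$; replicate values are
   normalized so the negative-control condition averages exactly 100 %,
   knockdown is $100 - \overline{\mathrm{norm}}$, and each condition is
   compared with the control by an equal-variance two-sided Student's
   t-test.

## 2. Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `spot_diameter` | 300 | µm | printed spot size of the assay |
| `edge_gap` | 200 | µm | spacing *between spot edges*; pitch = 500 µm |
| `margin` | 2000 | µm | unprintable slide border (see §5) |
| `um_per_pixel` | 1.33 | µm/px | 10× objective class |
| `cell_density` | 1500 | cells/mm² | subconfluent monolayer |
| `min/max_nucleus_area` | 30 / 500 | µm² | HeLa nuclei ~70–280 µm² |
| `smooth_sigma_um` | 1.0 | µm | pre-segmentation denoising |
| `marker_min_dist_um` | 4 | µm | watershed seed separation |
| `dilation_radius_um` | 3 | µm | perinuclear measurement ring |
| `association_radius_factor` | 1.0 | – | cells within one nominal radius |
| `control_percentile` | 0.05 | – | classification threshold (see §4) |
| `min_cells` | 20 | cells | below this a spot is flagged low-count |

## 3. The synthetic world

`render_field` / `render_well` generate ground-truthed three-channel
images so every downstream stage can be scored against known truth.

What is emulated:

* filled tracer discs at the layout's spot positions;
* one soft-edged nuclear blob per cell, radius drawn from
  N(7 µm, 1 µm) (HeLa-like, ~14 µm nuclear diameter);
* a per-cell phenotype intensity drawn from N(1000, 50) for expressing
  cells and N(100, 50) for silenced cells, painted over the nucleus
  dilated by the same 3 µm used at measurement time; a cell over spot
  *s* is silenced with probability `per_spot_silenced_fraction[s]`;
* Poisson shot noise on signal, additive Gaussian background
  (100 ± 10), 16-bit clipping;
* full determinism given `seed`.

**Cell placement** uses sequential random inhibition rather than a pure
Poisson point process: a candidate centre is rejected while it lies
within $0.8\,(r_i + r_j)$ of an already placed nucleus, and the
constraint is dropped for a cell after 30 failed attempts (so crowded
fields still overlap rather than losing density). Rationale: nuclei are
solid bodies. A uniform Poisson process at 1,500 cells/mm² puts ~10 % of
nuclei within 4 µm of a neighbour — closer than half a nucleus radius —
which real monolayers do not exhibit and which no segmentation can
recover, because the rendered image of two near-coincident equal discs
carries no trace of the second one. With inhibition, nuclei still touch
and partially overlap (the watershed split is genuinely exercised; see
the 30 %-overlap test), but biologically impossible coincidences are
excluded. Setting `nucleus_exclusion_factor = 0` restores pure Poisson
placement.

What a green test does **not** establish: real images add optical
point-spread blur, autofluorescence, uneven illumination, spot-morphology
defects (doughnuts, comets), debris, mitotic/apoptotic nuclei and
staining variability, none of which are modelled. Green acceptance means
the *algorithmic chain is correct and unbiased on its stated world*, not
that the pipeline is validated for production microscopy data.

## 4. Thresholds and numerical choices

* **Expression threshold.** The assay description defines the threshold's
  purpose (exclude low expressers) but not its derivation. The default is
  *control-anchored*: the 5th percentile of per-cell intensity among
  cells on negative-control spots of the same batch. Anchoring to
  controls makes batches comparable and fixes the control's expected raw
  percent near 95 %; the normalization then maps the control mean to
  exactly 100 %. Fixed-value and Otsu strategies are selectable
  (`pipeline_config(threshold_strategy = ...)`).
* **Per-cell intensity** is the *mean* intensity over the measurement
  region (area-independent); integrated total intensity is available via
  `intensity_statistic = "total"`. Whether the original analysis
  thresholded per pixel before aggregating, or per-cell means as done
  here, is not recoverable; the per-cell mean is the documented choice.
* **Otsu's method** maximizes between-class variance on a 256-bin
  histogram; across an empty gap between modes the criterion is flat, and
  the mid-plateau bin is returned (the lower edge would sit directly on
  the background shoulder). On images with no real signal Otsu still
  splits the noise, so automatic thresholding additionally requires the
  foreground class mean to clear the background by 3 background SDs;
  otherwise the image is declared empty rather than segmented into noise.
* **Distance transform**: exact Euclidean (Felzenszwalb–Huttenlocher
  two-pass), with a finite sentinel (1e20) instead of infinity because
  the parabola-intersection formula would produce NaN on fully
  foreground scan lines.
* **Watershed** is a marker-driven priority flood on the negated,
  lightly smoothed (σ = 0.5 px) distance map; markers are
  connectivity-grouped plateau maxima with a minimum separation of
  4 µm. No watershed *lines* are kept — every mask pixel joins a region.
* **Registration** estimates translation only. Printed arrays and the
  scanner stage are mechanically aligned, so rotation is assumed
  negligible; this is a documented limitation, not a measured fact.
* **Tie-breaks**: a cell equidistant from two spot centres goes to the
  lower spot id; greedy spot matching resolves conflicts nearest-first
  and leaves the farther detection unmatched.
* **Rounding**: control counts use deterministic half-up rounding
  (`round(3888 × 0.16) = 622`), since 16 % of 3,888 is not integral.
* **qPCR**: the original normalization ("cluster analysis with variable
  cluster endpoints") is not recoverable from its description; the
  standard $2^{-\Delta\Delta C_t}$ scheme is implemented instead, with a
  configurable amplification efficiency (default 2.0).
* **t-test**: equal-variance Student's t, because that is the named test
  for the replicate comparisons; a warning is emitted when group
  variances differ by more than 4×. On arrays the replicate unit is one
  spot; in plates, one well.

## 5. Open choices resolved here

* "Distance between spots of ~200 µm" is read as the *edge-to-edge* gap
  (pitch 500 µm): a 200 µm centre-to-centre distance would overlap
  300 µm spots. At that pitch a 26 × 76 mm slide with 2 mm margins holds
  44 × 144 = 6,336 spots, comfortably above the ~4,000 figure the assay
  was designed around; margins are not specified anywhere, and 2 mm per
  side is a conservative printable-area allowance.
* A 5-array set of 3,888 spots at 16 % controls provides
  5 × (3888 − 622) = 16,330 test positions. That does not equal the
  "18,000 open reading frames" the library nominally covers; the planner
  reports capacities and errors on overflow rather than resolving the
  discrepancy (a library of 16,330 labels fits exactly; 18,000 does
  not).
* Per-spot percentages are computed per replicate and then aggregated
  (not pooled across replicates before computing); low-count spots
  (< 20 cells) are flagged, never silently dropped.
* Nuclei touching the field border are kept and counted.

## 6. Known limitations

* Translation-only registration; no rotation/affine recovery.
* The baseline TIFF codec covers uncompressed grayscale 8/16-bit
  single-sample images only — sufficient for the package's own artifacts
  and common exports, not for compressed or tiled microscope formats.
* No optical PSF, illumination-gradient or spot-defect modelling in the
  generator beyond the options listed above.
* No multiple-testing correction beyond raw p-values, and no
  genome-scale hit-calling statistics (B-scores, robust z) — out of
  scope.
* Segmentation accuracy claims hold for the synthetic world's contrast
  regime (signal tens of noise-SDs above background); dim or highly
  textured nuclear stains will need parameter changes at minimum.
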
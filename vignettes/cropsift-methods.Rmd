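---
title: "Methods: sample mining, cross-year consistency filtering, and dual-length mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample mining, cross-year consistency filtering, and dual-length mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Supervised crop-type mapping needs large training sets, and field surveys
are the cost bottleneck. Historical crop-label rasters (annual CDL-style
products) offer labels for free, but they are imperfect: a direct draw of
(pixel, label, spectra) triples carries the product's own classification
error into the new model. `cropsift` implements a pipeline built around
two ideas:

* **Spatiotemporal sample selection.** Candidate pixels are restricted to
  the interiors of larger fields (a 5×5 label-homogeneous neighbourhood),
  avoiding mixed boundary pixels, and optionally to pixels whose label
  recurs across years of the same even/odd parity — the footprint of the
  two-year corn–soybean rotation.
* **Cross-year ensemble consistency filtering.** One classifier is trained
  per candidate year. A training-year candidate is retained only if the
  models of *all other years* unanimously predict its label; the held-out
  test year is voted on by the full bank. A mislabeled pixel's spectra
  still look like its true class, so other-year models — which never saw
  this year's label errors at this pixel — vote it down.

The filtered sample set then trains the final classifier (an MLP by
default), which is applied per pixel; a dual-length post-classification
merge removes a specific, structured confusion between rice and
transiently flooded wetlands.

# Time-series preparation

Monthly feature series are built per pixel and band in four steps, in this
order: acquisitions with a cloud fraction of 0.5 or more are dropped
(strict inequality keeps "less than 50% cloud"); the survivors of each
month are composited by the per-pixel masked **median** (robust to
residual cloud/shadow outliers and permutation-invariant); remaining gaps
are filled with the **mean of the nearest valid earlier and later
months**; the filled series is **Savitzky–Golay smoothed**.

Numerical choices:

* *Gap rule totality.* "Average of the phases before and after" is
  interpreted as *nearest valid* neighbours rather than strictly adjacent
  months — otherwise runs of consecutive gaps have no defined fill. A
  leading/trailing gap takes the nearest valid value. Pixels with fewer
  than two valid months cannot be filled and are flagged unusable; they
  are excluded from sampling and become nodata in maps.
* *Smoother.* Window 5, degree 2 — the shortest standard window usable on
  a six-month series. The filter reproduces polynomials up to degree 2
  exactly and is linear, so cubes are smoothed with one precomputed 6×6
  operator matrix. Smoothing runs after gap filling on a fully valid
  series; outputs are clipped to [0, 1].
* *Whether to smooth bands or an index* is genuinely open; bands are
  smoothed here, and indices can be built downstream from smoothed bands.

# The synthetic scene generator

All quantitative claims in this package are measured on synthetic scenes
with known truth, because the real inputs (satellite archives, historical
label products) are neither shippable nor verifiable offline. The
generator emulates the *structure* the pipeline exploits:

* **Fields**: axis-aligned squares (default 10 px) tiling the grid; every
  pixel of a field shares its class. This produces the field-interior /
  field-boundary distinction the 5×5 rule needs with minimal geometry.
* **Rotation**: crop fields alternate corn ↔ soybeans each year; rice is
  continuous (paddy infrastructure); the seven land-cover classes are
  static. Same-parity years therefore repeat crop labels exactly.
* **Phenology**: per class, band and month, a mean reflectance in [0, 1]
  (four broad bands: green, red, NIR, SWIR over May–October). Crop curves
  are unimodal NIR peaks offset in time; rice carries a water-like
  flooded signature in May and October. Classes are well separated over
  the full series but overlap pairwise in single months (soybeans and
  forest nearly coincide in August in all four bands), so single-month
  classification is measurably harder — the property behind the
  time-series-length experiment.
* **Noise**: i.i.d. Gaussian reflectance noise (default sd 0.02, a
  realistic post-compositing residual), clipped to [0, 1]; a fraction of
  (pixel, month) cells missing (default 5%); and label noise at a default
  10% — the order of error reported for real historical crop-label
  products. Label noise relabels pixels to a *uniformly random other
  class*; a per-field mode mimics the spatially correlated error of real
  products (the spatial error correlation of such products is not well
  characterized, so both modes are provided).

What the generator does **not** emulate: radiative transfer, real band
definitions, mixed pixels inside fields, class-structured label error,
geolocation error, and inter-annual phenology shifts. Passing tests
therefore demonstrate the pipeline's internal correctness and the
filter's behaviour under the stated noise model — not performance on any
real sensor.

# Classifiers

Four families share one train/predict surface, with per-band
standardization fitted on training data only (MLP and SVM need it; it is
harmless for trees):

* SVM (RBF, `C = 500` default), decision tree (gini, depth-capped,
  `min_samples_leaf = 10`, impurity threshold 0.001), random forest (100
  trees plus the tree settings), all via their standard R backends. Two
  backend mappings are documented rather than hidden: the tree backend
  caps depth at 30 (grid values above clamp), and the forest backend has
  no impurity-threshold stopping rule, so that hyperparameter is recorded
  but inert for forests.
* The **MLP**: hidden widths 16, 16, 32, 32, 64, 32, 32 and a 10-unit
  softmax head, batch normalization before every layer, dropout (default
  rate 0.2) after every hidden activation, tanh, Adam at learning rate
  0.001, batch size 8000. It is implemented in package code with analytic
  backpropagation — gradient-checked against finite differences in the
  test suite — and early stopping on a 10% validation split (patience
  10). The epoch budget and dropout rate are configurable because no
  reference values exist for them. When class labels lie in 1..10 the
  class list is padded to the full ten so the output head keeps its
  canonical width.
* `grid_search()` evaluates hyperparameter grids exhaustively with
  stratified 5-fold CV on mean overall accuracy; ties resolve to the
  first point in enumeration order. The MLP's `layers` axis (5, 7, 8) is
  interpreted as suffixes of the full width list — the full 8-layer
  topology is quoted explicitly, so it wins as the default, and shorter
  variants drop leading layers.
* Prediction is the probability argmax; exact ties resolve to the lowest
  class code, for determinism.

## Desk-scale optimization settings

The experiments ship with `mlp_bank_spec()`: batch 128, no dropout,
learning rate 0.003, epoch budget 600, patience 20. The reference
settings (batch 8000, dropout 0.2) presume on the order of a million
samples per year; at the few thousand samples per year used here they
collapse training to a single optimizer step per epoch and
over-regularize the small network, costing several points of worst-class
accuracy. Rescaling the optimization — while leaving topology, batch
normalization, activation and optimizer untouched — restores per-model
cross-year accuracy to ~99%.

# The reference experiments

The experiment functions freeze the study conditions; `scripts/acceptance.R`
re-runs them from scratch.

**Enrichment** (`enrichment_experiment()`): a 100×100, five-year, ten-class
scene with 10% pixelwise label noise; two acquisitions per month with 15%
extra cloud; 150 candidates per class per year (≈7,500 total). The
candidate draw *disables* the 5×5 homogeneity rule: under pixelwise noise
a mislabeled pixel almost never has 24 identically mislabeled neighbours,
so the homogeneity rule alone would eliminate essentially all mislabeled
candidates (0.9²⁵ ≈ 7% of pixels survive it) and leave the voting filter
nothing to act on. Disabling it puts ~10% label noise into the candidate
pool, which is the condition under which the filter itself is being
measured. (That the homogeneity rule is itself a powerful pixelwise-noise
filter is worth knowing when choosing selection rules for a real product
whose error is spatially uncorrelated.)

**Downstream benefit** (`downstream_experiment()`): both arms — candidates
vs. filtered — train the MLP on a stratified subsample of 25 points per
class and year and are scored on the held-out year against generator
truth. Uniform label noise cannot move the Bayes-argmax decision rule, so
with abundant, well-separated training data both arms sit at the same
ceiling and the comparison degenerates; at few samples per class the
mislabeled points distort the fitted boundary measurably, which is
exactly the scarce-label regime the sample-mining method targets.

**Series length** (`window_length_experiment()`): clean-label scenes;
nested windows {8}, {7,8}, {7–9}, {6–9}, {6–10}, {5–10}; random forest as
a fast, stable probe; kappa on the held-out year.

**Rice correction** (`rice_correction_experiment()`): a two-year 60×60
clean scene. Models for the full season and for June–September are
trained on year one; in year two every wetland field is "flooded" — its
May and October planes of the *prepared* cube are overwritten with the
rice signature plus noise. Applying the flood to the prepared cube
matters: smoothing a pre-flooded series would redistribute the
season-edge anomaly into June/September (the smoother's edge window spans
them) and contaminate the short window, which no real transient flood
does. This experiment's scene also has no missing cells: a gap-filled
August (replaced by the July/September mean) can flip a true rice pixel
in the short window for reasons unrelated to the correction rule, and the
experiment isolates that rule. The full-season model calls the flooded
block rice (the flooded months carry the strongest class evidence); the
short-window model, blind to the season edges, calls it wetland;
`correct_rice()` merges the two. The merge is idempotent, leaves every
non-rice pixel bit-identical, and can only shrink the rice area. A
probability-margin variant (replace only when the short window's best
non-rice probability beats rice by a margin) is provided for borderline
pixels but is not the default — the class-level merge is the documented
rule, and no reference value exists for the margin.

# I/O conventions

No GDAL-backed raster package is available to this build, so rasters are
stored as plain baseline TIFF plus a JSON sidecar holding grid metadata
(pixel size, origin, CRS label, year, months, bands, nodata convention).
Label rasters are 8-bit and round-trip exactly (codes 0–255, 0 = nodata,
matching the background convention of real label products). Reflectance
is stored as 16-bit scaled integers — the scaled-DN convention of
distributed reflectance products — so written values are quantized to
multiples of 1/65535 (≈1.5×10⁻⁵ reflectance), and values already on that
grid round-trip bit-exactly; validity masks are stored as an extra 0/1
page per month because baseline TIFF has no NaN-safe nodata for integer
samples. Sample tables are CSV with features printed at 17 significant
digits, which round-trips doubles exactly. Grids are checked for
identity, never silently resampled.

# Known limitations

* The label-noise model is uniform over wrong classes; real product error
  is class-structured (e.g. soybeans → corn) and spatially correlated.
  The per-field noise mode covers the spatial part; the class structure
  is not modelled.
* The filter never re-trains year models on their own filtered output;
  one pass is the defined procedure.
* Wetland flooding is injected, not emergent from a water-balance model;
  the correction experiment demonstrates the rule under its intended
  confusion structure, not the prevalence of that structure in any region.
* The MLP is CPU-bound pure R. It is entirely adequate at the package's
  sample sizes (thousands of rows, tens of features; seconds per fit) but
  is not a tool for million-sample training runs.
* Grid search over the full default MLP grid (162 points × 5 folds) is
  expensive; the tests exercise reduced grids, and practitioners should
  prune the grid before searching at scale.
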
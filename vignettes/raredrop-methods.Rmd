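---
title: "raredrop: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raredrop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredrop)
```

## Scope

`raredrop` models an immunofluorescence liquid-biopsy workflow for rare
circulating plasma cells in multiple myeloma and its precursor states
(MGUS, SMM, NDMM, RRMM). Peripheral-blood nucleated cells are plated on
slides, imaged in four channels — DAPI, CD138, BCMA and CD45 — and analyzed
as a funnel:

1. **simulate** (`generate_cohort`, `generate_frame`) — synthetic samples
   or rendered frames with full ground truth;
2. **segment/extract** (`process_frame`) — nuclear and cellular masks,
   morphometric and intensity features per event;
3. **detect** (`detect_rare_events`) — outlier clustering in a PCA-reduced
   feature space;
4. **curate** (`train_curation_model`, `apply_confidence_filter`) —
   gradient-boosted artifact rejection at a confidence threshold;
5. **phenotype** (`phenotype_events`) — 12 marker classes from CD138, BCMA
   (membrane vs perinuclear) and CD45 positivity;
6. **enumerate** (`enumerate_sample`) — cells per mL of blood;
7. **stats / predict** (`pairwise_state_tests`, `clinical_correlations`,
   `predict_disease_state`) — cohort comparisons and patient-level
   classification.

Every stage is deterministic given its seed, and `run_pipeline` ties the
stages together with checksummed artifacts.

## The synthetic truth model

Real rare-cell cohorts are not redistributable, so the package ships a
generator whose defaults *are* the study conditions for all quantitative
claims in the test suite.

**Channels and classes.** Marker truth levels are drawn far from the
decision boundary: negative channels are clipped to `[0, 30]` intensity
units, positive channels to `[70, 255]`, with a truth cutoff of 50. The
gap is deliberate — it makes ground-truth classes unambiguous so that
phenotyping errors measure the pipeline, not label noise. BCMA-positive
cells carry a localization (`membrane` or `perinuclear`) expressed both in
the tabular band scores and in the rendered ring/annulus geometry.

**Populations.** Background leukocytes (DAPI+, CD45+, CD138−, BCMA−)
dominate every sample. Rare-class counts are Poisson around
`incidence × effective analyzed volume`, where the effective volume is
`blood_volume × n_analyzed / CBC_total` (exactly 1 mL at the defaults:
8 mL draw, 6e6 nucleated cells/mL, 2 slides × 3e6 cells). Technical
artifacts (unstained blobs and saturated speckles with a single hot marker
channel, low solidity, high eccentricity) are added binomially.

**Incidence presets.** Per-state cells/mL presets rise from MGUS through
NDMM for the plasma-cell classes (e.g. `D | 138 | BCMA-Memb`:
1.0 → 2.73 → 3.45 → 3.61 across MGUS/SMM/NDMM/RRMM), while
leukocyte-like classes stay flat. These encode the *direction* of
published cohort findings; absolute group means and p-values from real
cohorts are not reproducible from simulation and are not claimed.

**Rendering.** `generate_frame` paints each cell as an eccentricity-
jittered ellipse pair (nucleus, cell) plus the BCMA localization band:
a membrane ring within 3 px outside the cell boundary, or a perinuclear
annulus 1–4 px outside the nucleus. Cells are placed without overlap;
frames that cannot hold the requested count fail loudly rather than
silently overlapping.

## Imaging

Nuclei are Otsu-thresholded in DAPI — with a background floor of
`median + 5·MAD` so a frame of pure noise yields zero nuclei — then split
by distance-map watershed and size-filtered. Cell bodies grow from
nuclear seeds by `EBImage::propagate`, restricted to marker foreground
(per-channel `median + 5·MAD`, robust to one very bright cell suppressing
a dim one), a maximum expansion, and a guaranteed minimum rim. Bright
objects with no nucleus become artifact candidates.

Feature extraction computes moment-based eccentricities, a 4-neighbour
boundary perimeter, convex-hull solidity, per-channel medians and MADs,
and the two BCMA localization scores. Two implementation notes matter for
anyone modifying this code:

* `EBImage::erode` binarizes label images, so the membrane band is
  computed by per-label binary erosion on padded bounding boxes;
* the membrane band and perinuclear annulus are kept disjoint — in thin
  cytoplasm the band would otherwise swallow the annulus and both scores
  would saturate together.

DAPI is summarized over the nucleus (it is a nuclear stain); whole-object
fallback applies only to anuclear artifact candidates.

## Rare-event detection

Features are robustly standardized (median/MAD, SD fallback), projected
onto principal components retaining 95% of variance, and each event gets a
Euclidean distance to the coordinate-wise median cell. The detection
threshold is the 99.5th percentile of those distances. Hierarchical
clustering (Ward) groups deviant events; the tree is cut at the largest
height whose clusters all have internal diameter at most
`cluster_cut_scale × threshold` (default scale 2). Events are flagged when
they sit in a cluster no larger than `max_rare_cluster_size`
(default `max(10, 0.1%)`) whose centroid reaches the threshold;
`max_rare_cluster_size = 1` bypasses clustering and reduces to the pure
threshold rule, which is the mode used for null-calibration checks.

The cut rule and the scale factor are repo choices: the underlying
procedure is published only as "PCA + hierarchical clustering against the
median cell", with no cut rule, linkage, metric or cluster-size cutoff
stated. All are exposed in `detection_params()` and echoed with
`provenance: repo-default` by `config_echo()`.

**Desk-scale caveat.** The q99.5 default targets genuinely rare events
(tens per million). Simulated demo cohorts are thousands of events with a
percent-level planted rare fraction, so the bundled demo config uses
`distance_quantile: 94` and a fractional `max_rare_cluster_size: 0.1`.
This is a property of the demo's scale, not a tuned accuracy knob: the
acceptance checks for recall/precision and null calibration run at the
defaults.

## Curation

A gradient-boosted tree classifier (`xgboost`, histogram method, single
thread for determinism) separates cells from artifacts. Model selection is
stratified k-fold CV over a small grid of depths and feature subsets,
capped by an evaluation budget; accuracies are always held out. Events are
kept when `P(cell) ≥ 0.90` — the confidence threshold is the one parameter
annotated `provenance: literature` in the config echo, since a 0.90
prediction-confidence cutoff is how such curation filters are typically
published, while every other default is a repo choice.

## Phenotyping and enumeration

Positivity cutoffs are estimated from the common population: an Otsu split
per channel identifies the negative mode, with a credibility check (the
two modes must separate by more than 3× the summed MADs). Channels without
a credible negative mode — CD45, because the leukocyte background is
CD45-positive — borrow the pooled negative mode of the other channels,
which is valid because the generator (like a normalized scanner) puts all
channels on a shared intensity scale. The cutoff is `median + 5·MAD` of the
negative mode; the DAPI gate is 0.25× the population's median DAPI.
Calls are inclusive at the cutoff. BCMA localization compares the two band
scores with a 1.2× dominance ratio (exact tie → membrane).

Enumeration applies
`cells/mL = count × (CBC_nucleated / n_analyzed) / blood_volume`,
evaluated in exactly that order so the identity is bit-reproducible
against independent arithmetic.

## Statistics and prediction

Group comparisons use the two-sided Wilcoxon rank-sum test — exact for
combined n ≤ 50 without ties (verified against full enumeration of rank
assignments), tie-corrected normal approximation otherwise, p = 1 for the
degenerate all-identical case. No multiplicity correction is applied to
the primary p-values; a Benjamini–Hochberg column is emitted alongside,
clearly marked as reference only. Clinical correlations use Spearman for
continuous variables and a standardized Wilcoxon z for binary ones.

Patient-level prediction evaluates univariate threshold stumps and
decision-tree / random-forest models on the 17 cells/mL features
(12 classes + 5 aggregates) with stratified repeated CV. Accuracies are
always held-out; an explicit `folds` argument lets callers group
duplicated or related samples into the same fold to prevent leakage.
Constant-on-fold features are dropped, with a majority-class fallback when
nothing varies.

## Known limitations

* The generator's tabular path draws features from the truth model rather
  than re-measuring rendered pixels; the imaging tests close that loop on
  a smaller scale by checking feature recovery on rendered frames.
* Intensity noise is Gaussian and channels are independent given class;
  real spectral bleed-through, focus drift and staining batch effects are
  not modeled.
* Published cohort headline numbers (specific p-values, means, prediction
  accuracies) depend on the real patient cohort and are out of scope; the
  package reproduces directions and self-contained printed quantities
  only.
* Survival analysis and bone-marrow flow cytometry are out of scope.

## Reproducibility

Every stochastic entry point takes a seed; `run_pipeline` derives stage
seeds from the master seed and writes md5 checksums of all artifacts.
Re-running a config reproduces every artifact byte for byte. The effective
configuration — including which values were user-set, repo defaults, or
literature values — is written to `config_echo.yaml` with each run.
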
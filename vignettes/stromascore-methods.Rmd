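---
title: "Methods: spatial scoring of tumor-stroma microenvironments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial scoring of tumor-stroma microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascore)
```

`stromascore` quantifies the spatial immune and stromal architecture of
tumor tissue from multiplex-immunohistochemistry (mIHC) single-cell tables
and relates it to relapse-free survival. This vignette documents the models
and conventions the package commits to, the parameters a user may want to
change, what the synthetic generators do and do not emulate, and the design
decisions taken where the underlying methodology left choices open.

## Input model

A *field* is a square region of tissue (default 1884 × 1884 µm, the field of
view of a 20× whole-slide scan crop) whose cells arrive as points: an
`x_um`/`y_um` coordinate pair plus one intensity column per marker. The
package does not perform nucleus detection, cell segmentation or image
registration; those belong to the upstream imaging stack. Patients
contribute between two and five fields depending on tumor size, and all
patient-level quantities are arithmetic means over fields.

## Tissue segmentation

Segmentation reconstructs three compartments from tumor-cell positions
alone:

- **Tumor mask.** Every pixel whose centre lies within `dilation_radius_um`
  (default 10 µm, about one cell radius) of a tumor cell. This turns the
  point pattern into the contiguous "tumor cell area". The rasterization
  step performs dilation only; morphological closing is deliberately left to
  the partition step so each operation has a single parameter and an
  analytic oracle (the dilation of one cell is a disc of area πr²).
- **Tumor nest (TN) and centre of tumor (CT).** The TN is the morphological
  closing of the tumor mask with a disc of radius `closing_radius_um`
  (default 20 µm): gaps narrower than twice this radius are absorbed into
  the nest. The CT is the hole-filling of the TN — the nest plus any stroma
  it fully encloses. This "filled closing" definition makes the CT an
  explicit object in a single-field pipeline (the original imaging protocol
  selected CT fields by eye).
- **Intratumoral stromal area (ISA).** ISA = CT \ TN, so TN and ISA are
  disjoint by construction and partition the CT exactly (asserted in pixel
  counts, the raster's machine precision).
- **Invasive front (IF).** The band of pixels outside the CT whose Euclidean
  distance to it is below `band_width_um` (default 300 µm, half-open so the
  boundary itself is front). Defining the band relative to the CT rather
  than the raw tumor mask guarantees the band and the centre are disjoint;
  a band around the raw mask could leak into enclosed stromal holes.

Rasters use a top-left origin, x right, y down, half-open 0-based pixel
intervals, and a default `grid_resolution_um` of 4 µm — about a cell radius,
at which the analytic fixtures (band of a square, annulus of a disc)
reproduce to well under 2% and halving the resolution moves areas by less
than 2%. Distances are measured centre-to-centre on the grid; at 4 µm this
biases band areas by at most half a pixel per boundary, which the fixture
tests bound.

Degenerate inputs follow three rules: an empty tumor mask yields an empty
TN/ISA/CT and an empty IF; a region that does not exist in a field (e.g. no
CT could be formed) carries area zero and produces *missing* densities, not
zeros; cells outside the field bounds are excluded with a warning rather
than clamped.

The nest/stroma rule is a reconstruction: the imaging platform it emulates
is described only as "a mathematical morphological approach", so the closing
radius, dilation radius and grid size are all exposed rather than baked in.

## Phenotyping

Marker positivity is anchored to fluorescence-minus-one (FMO) controls: the
threshold for a marker is the nearest-rank empirical quantile (the
⌈q·n⌉-th order statistic) of the FMO null sample, and a cell is positive only
when its intensity is *strictly* above the threshold — ties are negative,
consistent with the threshold being a null quantile. The quantile convention
is stated because sample-quantile definitions differ between tools.

Lineage gating is declarative: an ordered rule list in which the first rule
whose positive markers are all above threshold and negative markers all at
or below wins. The default tree gates tumor first (panCK⁺), so
double-positive conflicts such as panCK⁺αSMA⁺ resolve to tumor; CAFs require
αSMA⁺ with panCK, CD45 and CD31 negative; TAMs are CD45⁺CD68⁺ (M2 when
CD163⁺); TILs are CD45⁺CD3⁺ with CD8 recorded as a sub-flag; MDSCs are
CD45⁺myeloid⁺CD68⁻ with the myeloid marker configurable (default CD33; the
reference panel's exact MDSC markers are not public, so no fidelity claim is
attached to that default). The whole tree is replaceable via
`gating_config()` / YAML for other panels.

A note on the positivity quantile: the conventional default is q = 0.99, but
an empirical-quantile threshold has a built-in per-marker false-positive
rate of 1 − q on true-negative cells. With a 10-marker panel and conjunctive
rules, q = 0.99 therefore caps expected lineage accuracy near 97–98%
regardless of how well separated the positive populations are — each cell
has roughly a 1% chance of a spurious panCK call alone. The package's
fidelity validations consequently derive thresholds at q = 0.999 from a
10⁵-point null sample, where the family-wise false-call rate permits the
≥ 99% recovery the separable simulation model should achieve. Users gating
real panels should choose q with this arithmetic in mind.

## Quantification and scoring

- **Densities** are counts over region area (cells/mm²), computed per field
  and averaged per patient; missing regions propagate as missing values into
  medians and scores (mirroring cohorts where a CT field cannot be obtained
  for a small tumor). The combined CT region is reported alongside TN and
  ISA.
- **Immunoscore.** Four components — CD3⁺ and CD8⁺ density in a central
  region and in the IF — are scored 1 when strictly above the cohort median
  and 0 at or below it. The conventional variant uses CT + IF; the
  IS variant uses ISA + IF, restricting the score to peritumoral and
  intratumoral stroma. The total (0–4) classes patients as high (≥ 2) or
  low. When a component is missing the total runs over the remaining
  components against the unchanged ≥ 2 cut, and the missing count is
  reported; this keeps the one-missing-region patient in the cohort without
  inventing a density.
- **MMP14⁺ CAF/CAF ratio.** The fraction of CAFs in TN + ISA that are
  MMP14⁺. The IF is excluded from all CAF analyses because αSMA in the
  peritumoral band also stains smooth muscle. The patient value averages
  per-field fractions, consistent with the field-averaging rule used for
  densities; a pooled-count mode (`pooled = TRUE`) is provided because
  either reading of "the final value was calculated as the average" is
  defensible, and the two differ when fields have very unequal CAF counts.
  Fields with no eligible CAF are missing, not zero.
- **Median splits** everywhere use "≤ median → low", the same tie convention
  as the Immunoscore components, so a cohort of identical values is all-low.
- **Risk groups.** A = IS-high/ratio-high, B = high/low, C = low/high,
  D = low/low; group C (immunologically cold and MMP14-rich) is the adverse
  combination contrasted against the rest.

## Survival analysis

Kaplan-Meier estimation, the log-rank test and Cox proportional-hazards
fits are delegated to the `survival` package; `stromascore` wraps them in
tibble-returning `tidy()`/`glance()` methods. Committed choices:

- Efron tie handling (less biased than Breslow under ties; a `ties`
  argument exposes Breslow, which is exactly invariant to dataset
  replication and used as such in the tests).
- Wald 95% confidence intervals on the log-hazard scale; two-sided p-values
  throughout.
- Covariates are dichotomized indicators only — age (< 67 / ≥ 67), sex,
  location (right vs left/rectum), stage (IIIA-B vs IIIC), histology
  (favorable vs unfavorable), adjuvant regimen (5-FU vs oxaliplatin + 5-FU)
  plus the two biomarker classes — keeping the model surface identical to
  the clinical reference analysis; continuous covariates are out of scope.
- Fits with undefined coefficients abort; fewer events than terms warns.
- With zero events the log-rank statistic is undefined and reported as
  missing rather than zero.

## Expression screen

The screen takes a genes × samples matrix of normalized non-negative
values. Preprocessing removes genes whose *raw* value is below 1.5 in
strictly more than 50% of samples, then shifts all values by +1; the filter
is applied pre-shift (the threshold's scale is ambiguous in the source
description, so both the threshold and the fraction are arguments).
Co-expression with the target gene is ranked by Spearman's ρ (target
excluded). Differential expression splits samples at the target's median
(ties to the low group), computes per-gene log₂ fold change as the log ratio
of shifted group means — ratio-of-means, not mean-of-log-ratios, stated
because "log₂ fold change" underdetermines this — a two-sided Wilcoxon
rank-sum p-value, and Benjamini-Hochberg q-values over all tested genes.

## The synthetic generators

The generators exist so that every pipeline claim can be checked against
known ground truth; their defaults describe the study conditions the
pipeline targets, not estimates of any real cohort (no marker-intensity
distributions or per-lineage abundances are published for the reference
data).

- **Tissue fields** (`simulate_field()`): tumor nests are discs with
  log-normal radii (default median 185 µm). The default layout packs nest
  centres on a jittered square grid, emulating a centre-of-tumor field in
  which nests abut and enclose interstitial stromal corridors — the
  configuration under which a TN/ISA partition is meaningful; a uniform
  layout is available for sparser tumor areas. Cells are homogeneous
  Poisson: tumor cells at 2500/mm² inside the nest union, stroma (CAF 400,
  TAM 220, TIL 500, MDSC 60 per mm²) outside, figures chosen as plausible
  carcinoma magnitudes. Each lineage's markers draw log-normal positive
  intensities (median 10) over a common log-normal background (median 0.5,
  σ_log 0.6) that doubles as the FMO null; the ~20-fold separation makes
  gating fidelity a property of the rules rather than the noise. MMP14
  positivity is Bernoulli per lineage (tumor 0.35, CAF patient-specific,
  TAM 0.15, TIL 0.05, MDSC 0.10), qualitatively matching MMP14's
  predominance in tumor cells and CAFs.
- **Cohorts** (`simulate_cohort()`): each patient draws a true ratio class
  and TIL class (prevalence 0.5 each), a true MMP14⁺ CAF fraction
  (Beta(12, 6) for high, Beta(4, 12) for low — separated but overlapping),
  six binary covariates at the frequencies of the published 86-patient
  stage III table, and exponential survival under proportional hazards on
  the two biomarker indicators with independent exponential censoring.
  Default hazard ratios are 2.926 (ratio-high) and 0.277 (IS-high) — the
  multivariable effect sizes the pipeline is designed to detect — on a
  baseline of 0.006 events/month with censoring at 0.015/month, giving
  roughly 30% events over a five-year follow-up. With `fields = TRUE` every
  patient's fields are simulated with the patient's own CAF fraction and a
  TIL-density multiplier (×2 high, ×0.6 low) that drives the
  IS-Immunoscore.
- **Expression** (`simulate_expression()`): a latent factor per sample;
  the target is a log-normal transform of it, each planted correlate loads
  with latent correlation `rho_target`, a configurable fraction of genes is
  simulated below the 1.5 filter, and the rest are independent log-normal
  noise. Defaults (2000 genes, 592 samples) echo the scale of a public
  colorectal adenocarcinoma expression cohort.

One integer seed governs each generator call; per-patient and per-field
sub-seeds are drawn deterministically from it, so equal seeds give
bit-identical output.

**What the simulation does not emulate** — and what passing tests therefore
do not demonstrate about real tissue: irregular (non-disc) nest shapes,
spatial gradients or clustering of stromal lineages, correlated marker
noise and autofluorescence, segmentation and registration errors upstream
of the cell table, non-proportional hazards, informative censoring, and any
real cohort's actual effect sizes or median cutoffs. Validation on these
generators establishes internal correctness (geometry, conventions,
statistical calibration, parameter recovery), not clinical performance.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to make
Monte-Carlo error small relative to the asserted margins: analytic band
geometry on 3000 µm rasters at 4 µm; the TN/ISA partition and one-label
invariants on 100 random 900 µm fields spanning 0–12 nests and both
layouts; gating fidelity on three full-size fields (~23,000 cells);
Immunoscore enumeration over all 16 component patterns; Cox recovery on 50
cohorts of 400 patients with low censoring (Wald-CI coverage and the
group-C contrast); log-rank type-I error on 200 null cohorts of 86; FDR
null control on 300-gene noise matrices; and correlate recovery with 20
planted genes at ρ = 0.9 across 500 samples.

## Known limitations

- The TN/ISA rule is a morphological reconstruction with exposed
  parameters, not a reimplementation of the original proprietary platform.
- CAF identity rests on αSMA alone; other CAF markers (FAP, PDGFR, FSP1)
  and CAF subtypes are not modelled.
- The Cox layer offers no proportional-hazards diagnostics, time-varying
  covariates or competing risks.
- Immunocytochemistry cannot distinguish active from inactive MMP14, so the
  ratio counts expression, not activity.
- The expression screen covers correlation ranking and median-split
  differential expression; gene-set enrichment and immune deconvolution are
  external tools by design.
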
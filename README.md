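# stromascore

Spatial scoring of the tumor–stroma immune microenvironment from multiplex
immunohistochemistry (mIHC), with survival stratification and a target-gene
co-expression screen.

## The problem

In stage III colorectal cancer, outcome after curative resection depends not
only on tumor cells but on the composition and geography of the surrounding
microenvironment: cancer-associated fibroblasts (CAFs), tumor-associated
macrophages (TAMs, with the immunosuppressive CD163⁺ M2 subtype),
tumor-infiltrating lymphocytes (TILs) and myeloid-derived suppressor cells
(MDSCs). Two spatially resolved biomarkers are of particular interest:

- **MMP14⁺ CAF/CAF ratio** — the fraction of intratumoral CAFs
  (αSMA⁺ panCK⁻ CD45⁻ CD31⁻ cells in the tumor nest and intratumoral stroma)
  expressing the membrane-type collagenase MMP14; higher values mark an
  aggressive, desmoplastic phenotype.
- **Immunoscore** — a 0–4 score summing median-split indicators of CD3⁺ and
  CD8⁺ T-cell density over two tissue regions, with the stroma-restricted
  **IS-Immunoscore** variant scoring the invasive front (IF) and the
  intratumoral stromal area (ISA) instead of the whole tumor centre.

`stromascore` implements the full single-cell pipeline that turns per-cell
mIHC tables (coordinates in µm plus marker intensities) into these
biomarkers and their survival read-outs:

1. **Tissue segmentation** — rasterize gated tumor cells into a tumor-area
   mask; a morphological closing yields the tumor cell nest (TN), hole
   filling yields the centre of tumor (CT), the enclosed remainder is the
   ISA, and the IF is the band within 300 µm external to the CT boundary.
2. **Phenotyping** — derive per-marker thresholds as nearest-rank quantiles
   of fluorescence-minus-one (FMO) null samples; gate cells into lineages by
   ordered first-match rules (tumor = panCK⁺; CAF = αSMA⁺panCK⁻CD45⁻CD31⁻;
   TAM = CD45⁺CD68⁺ with M1/M2 by CD163; TIL = CD45⁺CD3⁺ with a CD8
   sub-flag; MDSC = CD45⁺CD33⁺CD68⁻).
3. **Quantification** — region-wise densities (cells/mm²) averaged over each
   patient's fields of view; both Immunoscore variants (ties at the cohort
   median score 0; total ≥ 2 is "high"); the MMP14⁺ CAF/CAF ratio over
   TN + ISA (the IF is excluded because peritumoral αSMA also stains smooth
   muscle); median-split classes; and the four risk groups
   A (IS-high/ratio-high), B (high/low), C (low/high — the adverse
   combination), D (low/low).
4. **Survival analysis** — Kaplan-Meier curves and log-rank tests,
   multivariable Cox proportional-hazards fits on the dichotomized clinical
   covariates plus the two biomarkers, and the group-C-versus-rest contrast.
5. **Expression screen** — on a genes × samples matrix: +1 shift, removal of
   genes below 1.5 in more than 50% of samples, Spearman ranking of
   co-expression with a target gene (e.g. *MMP14*), and median-split
   differential expression (log₂ ratio of group means, Wilcoxon rank-sum,
   Benjamini-Hochberg FDR).

Because the motivating patient cohort is not publicly deposited, the package
ships first-class **synthetic generators** — seeded simulators of tissue
fields (disc-shaped tumor nests, Poisson-placed cells, log-normal marker
intensities over an FMO-style background), patient cohorts with
proportional-hazards survival, and expression matrices with planted
correlates — that carry known ground truth for every downstream claim.

## Worked example

```r
library(stromascore)
library(dplyr)

# a small synthetic cohort with per-field single cells
coh <- simulate_cohort(cohort_sim_params(n_patients = 8), seed = 42, fields = TRUE)

# FMO-derived thresholds and the default 10-marker gating tree
thr <- derive_threshold_fmo(simulate_fmo_null(n = 1e5, seed = 43),
                            positivity_quantile = 0.999)
cfg <- default_gating_config(thr, positivity_quantile = 0.999)

prof <- profile_cohort(coh$cells, cfg)
prof$patients |>
  select(patient_id, mmp14_caf_ratio, ratio_klass, is_total, is_klass, group)
#> # A tibble: 8 × 6
#>   patient_id mmp14_caf_ratio ratio_klass is_total is_klass group
#>   <chr>                <dbl> <chr>          <dbl> <chr>    <chr>
#> 1 P001                0.0579 low                1 low      D
#> 2 P002                0.426  high               2 high     A
#> 3 P003                0.478  high               4 high     A
#> 4 P004                0.228  low                0 low      D
#> 5 P005                0.405  high               1 low      C
#> 6 P006                0.239  low                4 high     B
#> 7 P007                0.218  low                4 high     B
#> 8 P008                0.714  high               0 low      C
```

Each row is one patient: the field-averaged fraction of intratumoral CAFs
that are MMP14⁺, its cohort-median class, the IS-Immunoscore total (0–4) and
class, and the combined risk group. On a larger simulated cohort the Cox
machinery recovers the planted effect sizes:

```r
big <- simulate_cohort(cohort_sim_params(n_patients = 400, censor_rate = 0.002),
                       seed = 99)
fit <- cox_fit(big$patients,
               c("age_ge67", "female", "left_or_rectum", "stage_iiic",
                 "unfavorable_histology", "fu_monotherapy",
                 "true_is_high", "true_ratio_high"))
tidy(fit)
#> # A tibble: 8 × 5
#>   term                      estimate conf.low conf.high  p.value
#>   <chr>                        <dbl>    <dbl>     <dbl>    <dbl>
#> 1 age_ge67TRUE                 1.13     0.880     1.45  3.37e- 1
#> 2 femaleTRUE                   1.22     0.950     1.57  1.19e- 1
#> 3 left_or_rectumTRUE           1.18     0.907     1.53  2.18e- 1
#> 4 stage_iiicTRUE               1.14     0.835     1.56  4.04e- 1
#> 5 unfavorable_histologyTRUE    1.43     0.975     2.09  6.74e- 2
#> 6 fu_monotherapyTRUE           0.824    0.642     1.06  1.27e- 1
#> 7 true_is_highTRUE             0.332    0.255     0.432 2.73e-16
#> 8 true_ratio_highTRUE          2.80     2.17      3.62  4.23e-15

tidy(group_c_contrast(big$patients, group = "group_true"))
#> # A tibble: 1 × 5
#>   term             estimate conf.low conf.high  p.value
#>   <chr>               <dbl>    <dbl>     <dbl>    <dbl>
#> 1 group C vs A+B+D     3.82     2.85      5.11 1.99e-19
```

The two biomarker hazard ratios (simulated at 2.926 and 0.277) are recovered
with confidence intervals covering the truth, while the six clinical noise
covariates stay near 1; patients combining a low IS-Immunoscore with a high
MMP14⁺ CAF/CAF ratio (group C) carry a clearly elevated hazard.
`autoplot()` methods draw the segmented fields and Kaplan-Meier curves;
`screen_target()` runs the expression screen.

## Vignette

`vignettes/stromascore-methods.Rmd` documents the models, conventions
(raster geometry, tie handling, missing regions), default parameters and the
design decisions behind the pipeline, and what the synthetic validation does
and does not demonstrate about real tissue.
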
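# t1liver

Whole-liver histogram and texture analysis of quantitative T1 maps for
stratifying the risk of advanced fibrosis in nonalcoholic fatty liver
disease (NAFLD).

## Who this is for

Quantitative-MRI and radiomics researchers who want a fully testable,
self-contained reimplementation of the clinical T1-texture workflow:
variable-flip-angle (VFA) T1 mapping, semi-automatic whole-liver
segmentation, first- and second-order feature extraction, guideline-style
two-step risk labels, and the downstream statistics. No patient data are
required anywhere — a synthetic phantom and cohort generator provides
ground truth for every stage.

## The model in brief

**T1 fit.** Two spoiled gradient-echo magnitudes at flip angles 3°/15°
(TR = 4.61 ms) follow
S = M₀ sin(b₁α)(1 − E₁)/(1 − E₁ cos(b₁α)), E₁ = exp(−TR/T1),
with b₁ the transmit efficiency from a (resampled) B1 map. The two-point
DESPOT1 linearization y = E₁x + M₀(1 − E₁), y = S/sin α, x = S/tan α,
gives T1 = −TR/ln E₁ exactly.

**Segmentation.** Seeded random walker on the 6-connected voxel graph,
Gaussian edge weights w = exp(−β(gᵢ−gⱼ)²) + ε on [0,1]-normalized
intensities (β = 130); foreground probabilities solve the graph-Laplacian
Dirichlet problem; mask at probability ≥ 0.5.

**Features.** From the masked T1 sample: volume (cm³), mean, SD, median,
5th/95th percentile, skewness, excess kurtosis; and from a pooled
symmetric 3D GLCM (32 min–max gray levels, 13 unit offsets, log₂):
entropy −Σp log₂p, contrast Σ(i−j)²p, difference entropy and difference
variance of the gray-level-difference distribution.

**Risk labels.** NFS = −1.675 + 0.037·age + 0.094·BMI + 1.13·DM +
0.99·AST/ALT − 0.013·platelets − 0.66·albumin(g/dL);
FIB-4 = age·AST/(platelets·√ALT). FIB-4 or NFS in the low band (< 1.3,
< −1.455) ⇒ low risk; otherwise liver stiffness decides: < 8 kPa low,
8–<10 intermediate, ≥ 10 kPa high. Binary outcome: low vs
intermediate-to-high.

**Statistics.** Shapiro–Wilk-gated t / Mann–Whitney comparisons, stepwise
binary logistic regression (backward default), ROC with DeLong CIs and
Youden-optimal cutoffs, DeLong paired-AUC tests, Hosmer–Lemeshow
calibration, two-way mixed ICC with F-based CIs.

## Worked example

```r
library(t1liver)

# synthetic phantom: liver-shaped T1 field + SPGR pair + B1 + seeds
ph     <- phantom_spec(grid_shape = c(32, 32, 32), rng_seed = 7L)
bundle <- generate_phantom(ph)

# B1-corrected two-point VFA fit, then seeded random-walker segmentation
t1  <- fit_t1_vfa(bundle$spgr_low, bundle$spgr_high, bundle$b1_map)
seg <- random_walker_segment(bundle$spgr_high, bundle$seeds)
dice(seg$mask, bundle$truth_mask)
#> [1] 0.9892043

# propagate the mask to the T1 map and extract the 12 features
mask <- propagate_mask(seg$mask, t1)
round(unlist(extract_all(t1, mask)), 3)
#>        volume          mean            sd        median            p5
#>        22.384       969.256       265.804       953.766       542.018
#>           p95      skewness      kurtosis       entropy      contrast
#>      1416.864         0.129        -0.355         7.782         5.931
#>  diff_entropy diff_variance
#>         2.497         2.330
```

The phantom was simulated with liver T1 954.25 ± 278.17 ms: the fitted,
segmented, masked estimate lands within sampling error of both moments
(volume is in cm³; entropies in bits; kurtosis is excess kurtosis, so a
near-Gaussian field gives ≈ 0).

```r
# two-step risk stratification of one subject (albumin arrives in g/L)
rec <- clinical_record(age = 52, sex = "male", bmi = 31, dm = TRUE,
                       ast = 70, alt = 55, platelets = 160,
                       albumin = 42, albumin_unit = "g/L",
                       lsm_values = c(10.8, 11.2, 11.9, 12.1, 12.4,
                                      11.7, 12.0, 12.3, 11.5, 12.6))
s <- stratify(rec)
sprintf("FIB-4 %.2f, NFS %.2f, first line %s, final %s", s$fib4, s$nfs,
        s$first_line, s$final)
#> [1] "FIB-4 3.07, NFS 0.70, first line high, final high"
```

FIB-4 3.07 and NFS 0.70 both fall outside their low bands, so the liver
stiffness (median 12.0 kPa ≥ 10, series reliable) sets the final label:
high risk, binary positive.

An end-to-end run — cohort simulation, per-subject imaging chain,
stratification, and the univariate/ROC/model/ICC report written as CSV +
JSON under stage-numbered folders:

```r
res <- run_pipeline(default_config(n_subjects = 20, rng_seed = 1L),
                    out_dir = "scratch/demo")
```

## Layout

- `R/` — implementation (volumes + NIfTI I/O, T1 fit, segmentation,
  features, clinical scores, statistics, synthetic generators, pipeline)
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles in `helper-oracles.R`
- `vignettes/whole-liver-t1-texture.Rmd` — methods: model assumptions,
  parameter choices, what the synthetic world does and does not establish
- `inst/cli/t1liver.R` — command-line entry points (`simulate-phantom`,
  `fit-t1`, `segment`, `extract`, `stratify`, `run`)
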
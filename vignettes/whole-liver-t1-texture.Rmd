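---
title: "Whole-liver T1-map histogram and texture analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-liver T1-map histogram and texture analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1liver)
```

## The problem

Advanced fibrosis (F3–F4) is the dominant prognostic factor in nonalcoholic
fatty liver disease (NAFLD), but biopsy is invasive and poorly suited to
monitoring. Clinical guidelines therefore stratify risk noninvasively in two
steps: blood fibrosis scores (FIB-4, NFS) as the first line, and
vibration-controlled transient elastography (liver stiffness, kPa) as the
second. Quantitative T1 mapping offers a complementary imaging readout —
fibrosis and inflammation prolong T1, fat and iron shorten it — and the
*spatial organization* of T1 within the liver carries signal that a single
mean value discards. This package implements the full analysis chain from
raw two-flip SPGR images to a risk-stratified statistical report, with a
synthetic generator supplying ground truth at every stage.

## T1 mapping: model and fit

The spoiled gradient-echo steady-state signal at flip angle $\alpha$ is

$$S = M_0 \sin(b_1\alpha)\,\frac{1 - E_1}{1 - E_1\cos(b_1\alpha)},
  \qquad E_1 = e^{-TR/T_1},$$

where $b_1$ is the transmit-field efficiency (fraction of the nominal flip
angle). With exactly two flip angles (defaults 3° and 15° at TR = 4.61 ms,
the pairing that optimizes precision near a 1000 ms target T1) the
DESPOT1 linearization $y = S/\sin\alpha_{\rm eff}$,
$x = S/\tan\alpha_{\rm eff}$ turns the model into a straight line with
slope $E_1$, so the two-point solution is *exact* — an iterative fit adds
nothing and is kept only as a test oracle. Assumptions: ideal spoiling, TE
short enough that T2* decay is a common scale factor, and a B1 map that is
smooth enough to survive trilinear resampling onto the signal grid (the
clinical B1 is acquired at a much coarser matrix; the vendor's exact
interpolation scheme is unpublished, trilinear is our choice). Voxels whose
linearized slope leaves $(0,1)$ get the sentinel `T1_INVALID` and are
excluded from all masked statistics; a sentinel was preferred over NA
plumbing because every downstream consumer already filters through the
mask.

## Segmentation

The whole liver is segmented from the 15° image with the seeded
random-walker algorithm: on the 6-connected voxel graph with Gaussian edge
weights $w_{ij} = \exp(-\beta (g_i - g_j)^2) + \varepsilon$ (intensities
min–max normalized to $[0,1]$), the foreground probability of each
unseeded voxel is the harmonic solution of the Dirichlet problem
$L_U x_U = W_{US} m_S$. Choices, all conventional and all configurable
because the clinical prototype's values are unpublished:

* $\beta = 130$ on normalized intensities (standard random-walker
  practice);
* 6-connectivity, keeping the Laplacian sparse;
* $\varepsilon = 10^{-10}$ guards against disconnected components;
* mask threshold at probability 0.5, ties to foreground;
* systems up to 8000 unseeded voxels are solved with a sparse Cholesky
  factorization (exact), larger ones with Jacobi-preconditioned conjugate
  gradients to relative residual `solver_tol` (default $10^{-5}$).

Manual review is modelled by `refine_mask()` (logged voxel edits, mask
only — the probability field is evidence and stays untouched), and the
final mask is carried to the T1 map by `propagate_mask()` (metadata
re-association when grids are congruent, nearest-neighbour resampling
otherwise).

## Features

Eight first-order features of the masked T1 sample — volume (cm³), mean,
SD, median, 5th/95th percentile (linear interpolation, R type 7), skewness,
kurtosis — and four second-order features of a masked 3D gray-level
co-occurrence matrix: entropy, contrast, difference entropy and difference
variance. GLCM conventions are explicit because the vendor's are not
published, and they are recorded on every extracted vector:

* 32 equal-width gray levels over the masked min–max range (per volume);
* the 13 unique unit-displacement 3D directions pooled into one symmetric
  matrix — one value per liver, orientation-invariant;
* base-2 logarithms (entropies in bits), $0\log 0 \equiv 0$;
* `diff_variance` is the variance of the gray-level-difference
  distribution $\sum_k (k - \mu_{x-y})^2 p_{x-y}(k)$ (the original texture
  literature is ambiguous here);
* kurtosis is reported as *excess* kurtosis (normal ⇒ 0).

Because binning, offsets and log base all differ from the unknown vendor
configuration, published texture *magnitudes* are reproducible only in
ordering and direction, not value — the tests therefore assert direction
(e.g. diff-entropy higher in the high-risk group) and internal identities
(contrast $= \sum_k k^2 p_{x-y}(k)$; reflection invariance), never the
published absolute numbers.

One subtlety worth recording: with per-volume min–max binning, the
quantized labels of a field $\mu + \sigma z$ do not depend on $\mu$ or
$\sigma$ at all, so GLCM entropy is *scale-invariant* in the T1 SD. The
monotone SD→entropy property is real but manifests under fixed-range
binning (supported via `feature_config(range_rule = "fixed")`) or through
a shorter spatial correlation length; the test suite probes it in the
fixed-range regime, and the cohort generator separates groups through both
dispersion and correlation length.

## Clinical scores and the two-step rule

NFS $= -1.675 + 0.037\,\mathrm{age} + 0.094\,\mathrm{BMI} +
1.13\,\mathrm{DM} + 0.99\,\mathrm{AST/ALT} - 0.013\,\mathrm{platelets} -
0.66\,\mathrm{albumin}$ (albumin in g/dL) and FIB-4 $=
\mathrm{age}\times\mathrm{AST} / (\mathrm{platelets}\sqrt{\mathrm{ALT}})$.
Laboratory tables usually report albumin in g/L while the NFS formula takes
g/dL; ingest is explicit about units and a g/dL-declared value outside
$[1, 7]$ raises an error rather than silently producing a nonsense score.

A stiffness examination is *successful* with ≥ 10 valid measurements and
*reliable* if IQR/median ≤ 30%, or if the median is below 7.1 kPa when
IQR/median exceeds 30% (we read "less than 7.1 kPa" as referring to the
median — the source is not explicit). The two-step rule: a subject whose
FIB-4 **or** NFS falls in its low band (< 1.3, < −1.455) is low risk and
stiffness is never consulted; otherwise the final band is set solely by the
stiffness median (< 8 low, 8 to < 10 intermediate, ≥ 10 high). Boundary
semantics are fixed and tested exhaustively: 1.3/3.25 and −1.455/0.672
belong to the intermediate score bands, 8 kPa is intermediate and 10 kPa is
high. When both scores are non-low but disagree, the literal "or" only
defines the low case; we take the more severe band (configurable to the
less severe), since the original protocol does not say how discordance was
resolved.

## Statistical chain

* **Univariate:** Shapiro–Wilk at α = 0.05 on each group gates Student's
  t (equal variances, as named) vs Mann–Whitney; a constant group skips
  the gate to Mann–Whitney with a note.
* **Stepwise logistic:** backward elimination by Wald p (> 0.10 removes)
  is the default, matching the Methods wording of the source study;
  forward addition by likelihood-ratio p (< 0.05 enters, with removal
  re-checks) is available because its Results section names the opposite
  direction. Thresholds mirror common SPSS defaults. Perfect separation is
  flagged, elimination stops (Wald p-values are meaningless there) and
  coefficients come from a lightly ridge-penalized refit.
* **ROC:** empirical curve; AUC by trapezoid (= normalized Mann–Whitney
  U); 95% CI from the DeLong variance with a normal approximation, clipped
  to $[0,1]$ (the binomial-exact CI of some commercial tools is not
  replicated); cutoff maximizes Youden's J, ties to the lowest threshold.
  Positive class: intermediate-to-high risk.
* **DeLong comparison** of paired AUCs via structural components,
  two-sided normal p.
* **Hosmer–Lemeshow** with deciles of risk and $g-2$ df — the reference
  distribution that is valid for probabilities *fitted* by logistic
  regression, which is how the calibration-uniformity test simulates it
  (with known true probabilities the statistic is $\approx\chi^2_g$ and
  p-values would not be uniform).
* **ICC:** two-way mixed, single measure. Consistency form ICC(3,1) is the
  default (the source is silent; a constant reader offset arguably should
  not count against agreement), absolute agreement ICC(2,1) by flag;
  F-based CIs; bands poor/fair/moderate/good/excellent at
  0.2/0.4/0.6/0.8.

## The synthetic world

`generate_phantom()` builds: a liver as a union of 2–3 overlapping
ellipsoids (crudely liver-like, each component has an analytic volume
oracle); a within-liver T1 field as white noise smoothed by a Gaussian
kernel of width `heterogeneity_length` and rescaled to the target mean/SD
— two parameters control the marginal dispersion and the spatial grain of
the texture, which is exactly what the feature set measures; low-T1 tubes
("vessels") carved out of the mask so background seeds have something to
sit on inside the organ; a linear B1 gradient (default ±5%); and both SPGR
magnitudes forward-simulated through the signal equation with additive
Gaussian noise (Rician bias is ignored — at the simulated SNR of ~60–80
the difference is negligible). Default T1 statistics are the published
low-risk group marginals (954.25 ± 278.17 ms); the field is truncated at
50 ms, which perturbs the realized moments by well under the 5% sampling
tolerance at these parameter values. Seeds are auto-placed per the
clinical protocol: foreground on three axial slices near the top, middle
and bottom of the liver, background at the volume corners and inside
vessels.

`generate_cohort()` draws exactly `round(n · frac)` intermediate-to-high
subjects (so the published 33/20 split at n = 53 is reproduced, not merely
expected), group-conditional demographics and labs from the published
means/SDs (truncated normals with physiologic floors; sex and diabetes as
Bernoulli with published prevalences), and a log-normal stiffness series
per subject (≥ 10 values, within-series log-SD 0.12, so IQR/median lands
near 0.17 and the reliability rule is exercisable but not binding).
`label_fidelity` defaults to 1: the latent group *is* the two-step
stratification outcome, achieved by making first-line scores non-low for
high-risk subjects (diabetes set, then AST inflated — both clinically
sensible directions) and by drawing the stiffness median in the band
matching the label. Lower fidelity injects label noise for robustness
experiments only; it is not used in any test. Between-group typical
stiffness medians (5.5 vs 12 kPa) are our choice of a realistic gap —
nothing in the statistical acceptance depends on their exact values
because labels are recovered by construction.

What the generator does **not** emulate: real hepatic anatomy (no atlas),
fat/iron T1 confounding beyond a scalar fat-fraction covariate, k-space or
motion artifacts, non-axis-aligned acquisitions, or any within-liver
spatial statistics beyond a single stationary correlation length — the
published study reports only marginal feature values, so the correlated
field is one of many spatial models matching those marginals. A green test
therefore establishes that the *pipeline* is correct against stated ground
truth, not that the generator reproduces patient livers.

## Numerical choices and degenerate inputs

Quantization sends the masked maximum into the top bin; a constant masked
image maps to level 0 (valid, not an error). A single-voxel mask reports
SD 0 and undefined (NA) skewness/kurtosis. A GLCM with no valid pairs
(isolated mask voxels) is an error naming the cause. Empty masks error in
feature extraction but only warn (with a flag) in `refine_mask`, since an
over-aggressive manual edit is a reviewable state, not a broken one.
Random-walker probabilities are clipped of solver round-off to $[0,1]$ and
tested against a dense direct solve to $10\times$`solver_tol`. The
two-point VFA fit's sentinel voxels never enter any statistic.

## Known limitations

Texture magnitudes are convention-dependent (see above). The NIfTI reader
is deliberately minimal (axis-aligned affines, single 3D volumes). The
stepwise procedure inherits the usual caveats of p-value-driven selection;
it is provided because it is what the reproduced analysis chain specifies,
not as a recommendation. In-sample ROC of a fitted model (the
"multivariate model" row) is optimistically biased — the source analysis
is in-sample and no cross-validation is added, by scope.
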
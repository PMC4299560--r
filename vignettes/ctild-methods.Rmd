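---
title: "ctild: methods, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctild: methods, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
conventions behind each stage, the parameters that matter, what the
synthetic generators emulate (and deliberately do not), and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The problem

Interstitial lung disease in systemic sclerosis is conventionally graded
on HRCT by readers (the Warrick score) and monitored physiologically by
pulmonary function tests. Computer-aided densitometry replaces the
reader's grading of disease *extent* with a voxel count: after the lung
is isolated from mediastinum and chest wall, the fraction of lung volume
whose attenuation exceeds a fibrosis threshold is a continuous,
reader-independent extent measure. Validating such a measure requires
(i) a segmentation whose errors are small against ground truth,
(ii) a transparent density-mask definition, and (iii) the cohort
statistics linking the computer score to reader scores and PFTs. `ctild`
implements all three, plus generators that supply ground truth.

## 2. Segmentation

Candidate lung is every voxel in the inclusive band \[−1024, −200\] HU.
Numerical conventions, each fixed deliberately:

* **Band endpoints are inclusive**, and HU below −1024 are clamped to
  −1024 on volume construction (the CT air floor; DICOM stores integers).
* **Connectivity** is 8-neighbour within axial slices, with *no*
  inter-slice connectivity by default: at a 7 mm inter-slice spacing the
  anatomy moves too much between slices for 3-D connectivity to be
  reliable. A 26-connectivity 3-D mode (`connectivity = "3d"`) is
  provided for contiguous volumes.
* **Exterior air** is any in-band component touching the axial image
  border (exterior air and lung share the band; the body wall separates
  them). Components smaller than `min_component_voxels` (default 50) are
  specks and dropped.
* **Trachea removal**: the trachea and main bronchi form an air column
  that overlaps slice-to-slice even at 7 mm spacing, so a 3-D pass (run
  regardless of the in-plane mode) removes every surviving component that
  reaches the most superior slice and whose axial centroid lies in the
  central third of the plane in both axes. Clinically this step is manual
  editing; the rule automates the common case and
  `apply_manual_exclusions()` (per-slice polygons, even-odd rule on voxel
  centres) remains as the general mechanism.
* **Vessels** need no explicit handling at this stage: soft tissue
  (> −200 HU) is outside the band. A per-slice morphological closing
  (`closing_radius_vox`) can fill small vessel holes, but **defaults to
  off**: the phantom ground truth excludes vessel voxels, and a filled
  mask would disagree with both the truth mask and the "mask is a subset
  of the thresholded set" invariant. With closing enabled that invariant
  intentionally no longer holds — filling holes is its purpose.
* **Coordinates** are 1-based `(row, col, slice)` with slice 1 most
  superior, the idiomatic R translation of the 0-based
  `(slice, row, col)` convention used by array-oriented toolkits.

## 3. Densitometry

The fibrosis fraction is a ratio of voxel counts over the masked lung:

$$FF = 100\,\frac{N_{[-1024,-200]} - N_{[-1024,-700]}}{N_{[-1024,-200]}}$$

* **Boundary semantics**: a voxel at exactly −700 HU is *nonfibrotic*;
  the fibrotic band is the half-open (−700, −200\]. The −700 threshold is
  the conventional upper bound of normal aerated parenchyma (normal lung
  is reported between about −800 and −900 HU); both edges are exposed as
  parameters because the literature also uses −700 to −500 for ILD and
  −500/−800 for ground-glass analyses.
* Fractions are voxel-count ratios, equivalently volume ratios at uniform
  spacing. No interpolation is attempted across the 7 mm slice gaps: the
  sampled slices are treated as a representative sample of the lung, as
  is standard when extent percentages are derived from gapped HRCT.
* Histogram descriptors are computed over the in-band masked voxels with
  population moments: MLA is the mean; skewness $m_3/m_2^{3/2}$; kurtosis
  $m_4/m_2^2$ **un-excess** (normal = 3), with `excess = TRUE` available
  since the convention is not universal. A constant histogram makes the
  higher moments undefined: `histogram_descriptors()` signals a
  `ctild_zero_variance_error` carrying the still-defined MLA, and
  `fibrosis_fraction()` reports them as `NA`.
* An empty masked band is an error, never a silent zero.

## 4. Warrick scoring

Severity points (1, 2, 3, 4, 5 for ground-glass, irregular pleural
margins, septal/subpleural lines, honeycombing, subpleural cysts) are
summed over abnormalities present in at least one segment; extent grades
(1–3 segments → 1, 4–9 → 2, >9 → 3) are summed per abnormality. This
per-abnormality reading is the only one consistent with the published
0–30 range (5 + 10 + 15 severity max plus 3 × 5 extent max). An
abnormality listed with zero segments is treated as absent; counts above
18 (the standard bronchopulmonary segment count) warn but grade as 3.
The mild/severe dichotomy is strict: total ≤ 7 mild, > 7 severe, with
the cutoff a parameter because it is an external criterion, not part of
the score.

## 5. The phantom generator

The phantom emulates exactly what the downstream stages consume: distinct
attenuation compartments in plausible geometry, not anatomy. Defaults:
air −1000 HU, normal lung −850 HU, fibrotic lung −600 HU (inside
(−700, −200\]), soft tissue +40 HU; grid 96 × 96 × 12 at 2 × 2 × 7 mm
with a nominal 1.25 mm slice thickness — sparse axial samples, as in a
gapped HRCT protocol. Additive Gaussian noise (default SD 30 HU, a
realistic parenchymal noise level for such protocols) is applied before
integer rounding; the ground truth (mask and fibrotic fraction) is
recorded before noise.

Exactly `round(f · n_lung)` lung voxels are made fibrotic, chosen by a
subpleural-preference score with seeded jitter — fibrotic ILD is
peripherally predominant, and the ragged edge avoids a trivially
separable fibrotic region. Because the count is exact, noise-free
recovery of FF is exact, which the tests assert.

Not emulated, deliberately: lobar anatomy, airway trees beyond a trachea
stub, honeycomb cyst microstructure, beam-hardening or motion artefacts,
and the ground-glass/reticulation/honeycombing distinction (the density
mask itself cannot separate these — a known limitation of the method).
A green phantom test therefore establishes correctness of the
*computational* chain, not clinical performance.

## 6. The cohort generator and its calibration

The generator draws one latent multivariate-normal vector per patient and
transforms each margin (a Gaussian copula / NORTA construction):

* **CaM extent** and the **Warrick reader scores** get scaled-beta
  margins (on \[0, 100\] and \[0, 30\]) matching the target mean/SD
  exactly. A plain normal-plus-clipping generator cannot meet its own
  plausibility constraint here: with Warrick 12.1 ± 6.9, about 4–5% of
  normal draws fall below zero, and clipping that mass distorts moments
  and correlations. With bounded beta margins the clipping guard is
  retained but essentially never fires (asserted at n = 10⁵ in the
  tests). The beta margin is also right-skewed, qualitatively matching a
  score distribution whose printed mean/SD sit far above its severe/mild
  split.
* **PFT percentages** stay normal (their out-of-range mass at the
  published moments is < 10⁻⁵).
* **Defaults** are the published cohort: 38 dcSSc + 41 lcSSc; CaM moments
  from the printed subtype mixture (22.1 ± 9.7 and 16.3 ± 9.0, giving
  19.09 ± 9.78 overall); Warrick 12.1 ± 6.9; FVC 89.6 ± 9.6,
  FEV1 83.8 ± 8.7, DLco 70.1 ± 15.9; CaM correlations 0.829 (Warrick),
  −0.490 (FVC), −0.675 (FEV1), −0.653 (DLco); reader ICC 0.81.

**Correlation completion.** Only the CaM row of the correlation matrix is
published. The rest is completed as if all variables loaded on a single
latent severity factor with CaM as its proxy:
$r_{ij} = r_{\mathrm{cam},i}\, r_{\mathrm{cam},j}$. Such a one-factor
matrix is automatically positive semi-definite; `nearest_psd()`
(eigenvalue floor 10⁻⁶, rejection below −0.1 naming the eigenvalue)
guards user-supplied matrices and the post-calibration latent matrix.

**Reader split.** Reader scores are
$r_j = \mathrm{round}(g(\sqrt{t}\,z_w + \sqrt{1-t}\,\varepsilon_j))$,
$j = 1, 2$, with $g$ the beta margin transform. The single-reader SD is
chosen so that the *mean-of-readers* column has the target SD
($\sigma^2_{\mathrm{single}} = 2\sigma^2_{\mathrm{mean}}/(1+\rho_{rr})$),
rounding is treated as additive variance 1/12 (Sheppard), and $t$ is
solved so the two rounded reader columns have the intended product-moment
correlation. With identical margins and no rater bias the population
ICC(2,1) equals that correlation.

**Calibration to expected sample statistics.** Targets are interpreted as
the *expected sample statistic at the design cohort size*
(`calibrate_to_n`, default 79) — this is what a replication study can
check. Three corrections connect the latent correlations to that goal:

1. the NORTA margin attenuation, inverted per pair by Gauss–Hermite
   quadrature (64 nodes) and root finding;
2. the mean-column conversion for pairs involving Warrick (factor
   $\sigma_{\mathrm{mean}}/\sigma_{\mathrm{single,cont}}$);
3. small-sample estimator bias. For Pearson r between CaM and the PFTs
   the normal-theory first-order bias $-\rho(1-\rho^2)/(2n)$ is
   compensated. For pairs involving the Warrick mean column, replication
   on development seeds showed the measured bias to be null within a
   standard error of 3 × 10⁻⁴ — the independent reader-noise and rounding
   components change the estimator's fourth-moment structure — so no
   compensation is applied there. For ICC(2,1) the estimator is *more*
   biased than Pearson r of the same magnitude (its mean squares estimate
   subject and rater means); replication (30 000 simulated cohorts of
   n = 79 at ICC 0.81 on development seeds) measured −0.00274 ± 0.00024
   against the normal-theory −0.00176, and the compensation uses the
   measured factor 1.55 (`ICC_BIAS_FACTOR`). These coefficients are
   estimator-bias measurements made once during development on seed
   ranges disjoint from any test seed; they are not tuned to test
   outcomes.

**Subtype assignment.** dcSSc status is given to the 38 patients ranking
highest on a noisy copy of the latent severity, $z_{\mathrm{cam}} +
\mathcal N(0, \sigma_s^2)$. Under a normal approximation the expected
subtype gap in CaM is $\sigma_{\mathrm{cam}}\,\rho_u\,\varphi(q)
(1/p_1 + 1/p_2)$ with $\rho_u = 1/\sqrt{1+\sigma_s^2}$ and $q$ the
selection quantile; solving for the printed 5.8-point gap gives
$\sigma_s \approx 2.5$. The approximation is mildly conservative under
the beta margin (the realized gap runs slightly under 5.8); the gap is a
realism feature, not a calibration target.

**What a green closure test establishes.** That the generator's emitted
columns reproduce the published means, SDs, correlations and reader
agreement in expectation at n = 79 — i.e. the downstream statistics
module, fed data with the published structure, recovers the published
structure. It does not establish anything about real HRCT images, and
two published inconsistencies are knowingly left unresolved: the 79
enrolled vs 80 ROC denominators, and a severe/mild split (41/39 at
cutoff 7) that is hard to reconcile with mean 12.1 ± 6.9 under any
unimodal margin (the skewed beta narrows but does not close that gap).

## 7. Statistics conventions

* **Pearson/regression**: direct product-moment formulas; two-sided p
  from the t transform with n − 2 df; zero variance is an error.
* **ICC**: ICC(2,1) — two-way random effects, absolute agreement, single
  measure — as the primary form, because the readers are interchangeable
  "random" raters and systematic offsets between them should count
  against agreement. The consistency form is exposed for comparison and
  equals 1 under a pure constant shift where the agreement form does not.
* **Group comparisons**: classical pooled-variance t; Pearson chi-square
  *without* Yates continuity correction.
* **ROC**: criteria are the distinct score values plus one below the
  minimum; positive means score **strictly above** the criterion (the
  ">c" row convention of criterion tables). The trapezoidal AUC over
  this staircase is algebraically the Mann–Whitney pair-counting
  estimate with ties counted one half — the suite asserts the identity
  to 10⁻¹². SE by Hanley–McNeil. The optimal threshold maximizes
  Youden's J, taking the smallest criterion on ties (reported
  operating points should favour sensitivity when indifferent).
* **Criterion table**: exact Clopper–Pearson 95% CIs for sensitivity,
  specificity and predictive values; likelihood-ratio CIs by the log
  method; +LR omitted where specificity is 100% (division by zero), −LR
  0 with an undefined CI at sensitivity 100%. Predictive values are
  computed transparently from the observed confusion counts, not
  prevalence-adjusted: the published table's PV columns cannot be
  reproduced from its own sensitivity/specificity/prevalence, so the
  auditable definition is used and documented.
* P-values are reported at machine precision; published "P < 0.0001"
  statements are bounds, not targets.

## 8. Input/output

Volumes travel as a plain-text slice series preserving the DICOM
behaviours the pipeline depends on — stored integers mapped to HU by
rescale slope/intercept, slices ordered by recorded position (file names
are ignored), series-UID coherence enforced, missing rescale tags
reported by name — because no binary DICOM/NIfTI reader can be assumed in
the deployment environment. Pipeline configuration is JSON for the same
reason. The pipeline writes a run manifest (config hash, package version,
MD5 checksums per stage) so any numeric output can be reproduced from its
configuration and seed; numeric reports contain no timestamps and are
byte-identical across reruns.

## 9. Known limitations

* The density mask cannot distinguish ground-glass, reticulation and
  honeycombing, and low-attenuation honeycomb cysts can *under*estimate
  severity while residual vessels above −500 HU *over*estimate it; the
  package mitigates the latter only through segmentation-stage
  exclusions, as the underlying method does.
* The trachea rule assumes the airway column is central and reaches the
  top slice; unusual geometry needs `trachea_policy = "none"` plus
  manual exclusions.
* Phantom realism is limited to attenuation compartments; segmentation
  Dice near 1 on phantoms does not predict clinical Dice.
* The cohort generator reproduces second-order structure (moments,
  correlations, ICC); higher-order features of real cohorts (floor
  effects, reader drift, missingness) are not modelled.
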
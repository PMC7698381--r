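---
title: "Quantifying intra- and inter-site tumor heterogeneity on multi-lesion CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra- and inter-site tumor heterogeneity on multi-lesion CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

High grade serous ovarian carcinoma (HGSOC) typically presents as
multi-site disease: an adnexal mass plus omental, peritoneal and serosal
implants. Because the disease is genomically heterogeneous both within and
between sites, a biopsy of one lesion is a poor summary of the whole tumor
burden, and radiomic descriptors computed on a single lesion inherit the
same blind spot. `iish` implements an imaging statistic — cluster
dissimilarity, **cluDiss** — that summarizes texture heterogeneity *within*
each lesion and *between* all lesions of a patient in one number, together
with the surrounding machinery a study of such a marker needs: a 75-feature
per-patient average-radiomics extractor, integrated
radiomic–clinical–genomic risk scores, a platinum-resistance classification
protocol, robustness and correlation screens, and a synthetic phantom
generator that makes the whole chain testable without any image downloads.

# The cluDiss pipeline

The measure is computed in six stages, all driven from
`cludiss_for_patient()`:

1. **Intensity normalization.** CT intensities are min–max rescaled to
   0–255 and discretized into 32 gray levels (`rescale_discretize()`). The
   reference range is taken over the union of lesion voxels by default
   (`rescale_scope = "lesions"`), i.e. a tumor-focused window; the whole
   image can be used instead. A degenerate range maps everything to level 1
   with a warning rather than failing.
2. **Per-voxel Haralick maps** (`haralick_maps()`). An 11 × 11 × 1 patch
   slides over every lesion voxel; a symmetric gray level co-occurrence
   matrix (GLCM) is pooled from the four in-plane offsets at distance 1,
   restricted to voxel pairs where *both* endpoints lie inside the patch
   and inside the lesion mask, so peritumoral fat and air never
   contaminate the statistics (the mask restriction is this package's
   choice and is recorded in the configuration). The GLCM is normalized to
   sum 1 and reduced to energy $\sum p^2$, entropy $-\sum p \log_2 p$
   (with $0\log 0 := 0$), homogeneity $\sum p/(1+|i-j|)$ and contrast
   $\sum p (i-j)^2$. A patch with no valid pairs takes the degenerate
   single-cell convention (1, 0, 1, 0).
3. **Subregion extraction** (`segment_subregions()`). Each lesion is
   partitioned into at most five texturally homogeneous subregions by
   kernel K-means on a seven-channel voxel descriptor: the four Haralick
   values plus the spatial coordinates, all z-scored, with the spatial
   channels down-weighted (`spatial_weight = 0.1`) so clusters are
   texture-driven but spatially coherent. The RBF bandwidth is the median
   pairwise descriptor distance on a subsample (at most 2000 voxels);
   k-means++ seeding with 10 restarts and a per-lesion derived seed makes
   the result reproducible to the last bit.
4. **Model selection.** The number of subregions per lesion is chosen by a
   cluster-separation validity rule: the largest k whose cluster mean
   descriptors are all at least 3 units apart in the z-scored texture
   space, with no cluster below 2% of the lesion (floor 5 voxels). Two
   AIC-style criteria (`"wcss_aic"`, `"mixture_aic"`) are available behind
   the same configuration switch, but measurements during development
   showed both to over-segment severely: descriptors of neighboring voxels
   come from overlapping patches and are therefore strongly spatially
   autocorrelated, so *any* spatial split of a perfectly homogeneous
   lesion gains far more log-likelihood than a fixed parameter penalty can
   absorb (on homogeneous phantom lesions the penalized criteria selected
   k = 5 almost always, while the separation rule selects k = 1
   essentially always and still recovers planted two-class structure with
   &gt; 99% voxel agreement). The separation rule is also the direct
   operationalization of "texturally distinct": a split only counts when
   the resulting clusters differ by more than the lesion's own descriptor
   scale.
5. **Dissimilarity structure.** Each subregion is described by the mean of
   its four Haralick maps; `dissimilarity_matrix()` computes all pairwise
   Euclidean distances between these raw 4-vectors, pooled across lesions.
   `build_gdm()` then summarizes them as a K × M (default 10 × 10) *group
   dissimilarity matrix*: pairwise distances are min–max normalized per
   patient and cut into K equal-width levels; for each subregion and
   level, the *group size* counts how many partner subregions sit at that
   dissimilarity level; the positive group sizes are min–max normalized
   into M levels; and G(i, j) counts (subregion, level) entries. Both
   min–max normalizations treat a numerically degenerate range (all
   values equal to ~1e-9 relative tolerance) as a single level.
6. **The statistic.** With normalized indices $u_i = i/K$, $v_j = j/M$ and
   entry weights $P = G / \sum G$,
   $$\mathrm{cluDiss} = \frac{1}{KM} \sum_{i=1}^{K}\sum_{j=1}^{M}
     (u_i + v_j - \mu_D - \mu_A)^4 \, G(i,j),$$
   where $\mu_D = \sum_i u_i P_{i\cdot}$ and $\mu_A = \sum_j v_j
   P_{\cdot j}$ are the normalized mean dissimilarity level and group
   size. G enters as **raw counts**, so the statistic grows with the
   number of subregions and hence with the number of texturally distinct
   lesions — the property that links it to tumor burden. A patient with
   fewer than two subregions in scope scores 0; a patient with fewer than
   two lesions in the requested anatomic scope (`all`, `pelvis`,
   `abdomen`) is flagged not evaluable rather than scored.

Two conventions in stage 5–6 deserve comment because the construction is
genuinely ambiguous in prose descriptions of such histograms. First, the
GDM here counts *dependence-style* entries (per subregion, per occupied
level) rather than raw pairs; this makes "group size" well-defined and
mirrors the logic of neighborhood gray level dependence matrices. Second,
the fourth moment uses bin indices normalized to (0, 1] rather than raw
indices. Because of these choices, published cut-offs for cluDiss-type
scores (the package ships 68.62 for cluDiss and 642.00 for the integrated
score as documented defaults) should not be expected to transfer
numerically to values computed here; refit cut points with
`find_cutpoint()` on your own cohort. The single-cell and
dependence-counting conventions are frozen by oracle tests.

# The 75 average-heterogeneity features

`extract_features()` computes a fixed manifest of 75 per-patient features
over the pooled voxels of all lesions ("across all disease sites"):
first-order moments (4), GLCM (5), gray level run length (13), gray level
size zone (13, including GLN and SZN), neighborhood gray tone difference
(5, including coarseness), neighboring gray level dependence (15,
including DCN), Sobel magnitude statistics (4) and Gabor magnitude
statistics at orientations 0°/45°/90°/135°, wavelength 2 px, bandwidth
√2 (16). Matrix families follow IBSI definitions with 3D 26-neighborhood
offsets merged before statistics; dependence counts use tolerance
α = 0 and include the center voxel (counts start at 1). Filter families
are applied slice-wise to the rescaled (0–255) image with replicate
borders, and summarized by mean, SD, skewness and kurtosis of the response
magnitude over lesion voxels; the Gabor magnitude combines the even and
odd kernels. Pooled accumulation is the default because the burden
sensitivity of the non-uniformity counts (GLN, DCN, SZN) is exactly what
makes them track total tumor volume in patients;
`aggregation = "volume_weighted"` switches to per-lesion computation with
voxel-count weights. All features operate on the rescaled intensities, so
adding a constant to the raw image changes nothing — an invariance the
test suite asserts.

Where a published linear score names a Gabor term without a statistic
suffix, the mean is used; the orientation/wavelength naming in this
package is `Gabor<angle>.<stat>` (e.g. `Gabor90.mean`).

# Integrated risk scores and the classification protocol

`score_preset()` ships the three published coefficient sets (iRCG, CCG,
aRCG) and `evaluate_score()` applies them as plain linear arithmetic in
raw units: age in years, copy number burden (CNB) as a genome fraction in
[0, 1], cluDiss as computed, cytoreduction outcome encoded ordinally
(complete = 0, optimal = 1, suboptimal = 2), FIGO stage III = 0 / IV = 1.
Raw units are the defensible reading because the published cut-off
(642.00) matches raw-unit magnitudes (≈ 4.44·69 + 3.72·59 + 2.11·0.5).
Dichotomization puts the boundary in the high-risk group (high iff score
≥ cut-off). New scores are fit with `fit_linear_risk_score()` (elastic net
via glmnet; the one-standard-error rule is the default tuning because it
gives the sparse solutions a small-cohort risk score needs) and new cut
points with `find_cutpoint()` (Youden index, ties toward the lower
cutoff).

`train_platinum_classifier()` implements the resistance-classification
protocol: repeated stratified 3-fold cross-validation (default 100
repetitions) of a linear SVM, with feature standardization and SMOTE
minority oversampling fit on each training fold only — held-out folds are
never oversampled and never influence the synthetic samples. SMOTE is
implemented in-package (k = 5 minority-neighbor interpolation) since no
implementation is available among the package's dependencies. Decision
values are explicitly oriented toward the resistant class before any AUC
is computed. Out-of-fold predictions are aggregated per repetition into
AUROC/sensitivity/specificity, with percentile 95% intervals over
repetitions; variable importances are absolute standardized weights
scaled to max = 100. The average-radiomics variant adds recursive feature
elimination with nested 3-fold inner CV over candidate sizes
{5, 10, 15, 20, 25}. `compare_classifiers()` reports a paired Wilcoxon
test on per-repetition AUROCs plus a DeLong test on pooled out-of-fold
scores.

One statistical subtlety discovered while validating the protocol: on a
*fixed* null dataset (labels carrying no signal), cross-validated AUROC is
not centered at 0.5 — finite-sample splits make training and test class
means negatively dependent, biasing the estimate pessimistically, and the
dataset-level variance is large (SD ≈ 0.07 at n = 60 with 14/46
imbalance). Calibration statements about the protocol therefore average
over permuted-label draws; the tests do exactly that.

`scanner_robustness_screen()` keys on the *absence* of a scanner effect: a
feature is robust iff its two-sided Wilcoxon rank-sum p-value exceeds
0.05; constant features are flagged and assigned p = 1.
`correlation_screen()` reports tie-corrected Spearman ρ with unadjusted
p < 0.05 flags (the convention of the radiogenomic literature this serves)
*and* Benjamini–Hochberg q-values, clearly separated. Survival
associations are thin contracts over the survival package: `coxph` hazard
ratios with Wald intervals and concordance, Kaplan–Meier strata with
log-rank p-values. None of that machinery is re-derived here.

# The phantom generator

`make_patient()` builds multi-lesion CT phantoms: ellipsoidal lesions on a
96 × 96 × 32 grid at 1 × 1 × 3 mm, each filled with a stationary Gaussian
random field (white noise smoothed at the class correlation length, then
scaled to the class mean/SD). Multi-class lesions are split into
equal-width sub-lobes **along z**: the texture patch is in-plane, so a
slice boundary produces no mixed-patch voxels and ground-truth voxel
labels remain exact — boundary effects of in-plane class interfaces are a
real phenomenon the generator deliberately avoids so that
clustering-recovery tests measure clustering, not interface geometry. All
randomness flows from a single seed through documented per-patient
derivations, so any subset of a cohort is reproducible.

Texture realism is deliberately minimal: the fields have no CT physics,
no scanner kernels, no contrast phases, and no anatomical context.
Passing tests on these phantoms therefore demonstrates that the
*computational chain* behaves as specified (recovery, monotonicity,
calibration), not that the marker is prognostic in real patients — that
question needs real cohorts.

Two palettes are provided. `default_texture_classes()` spans noise
amplitude and correlation length for general use.
`paired_texture_classes()` is the load-bearing fixture palette for
heterogeneity-response checks; its design follows three measured
properties of the pipeline:

* within a pair, the "coarse" (higher amplitude, shorter correlation)
  and "fine" members are separated by ≳ 4 z-units in descriptor space, so
  the two lobes of a lesion are recovered essentially always;
* all classes are spatially smooth, keeping the heavy-tailed GLCM
  contrast channel small so that descriptor dissimilarities — and hence
  the GDM level structure — are reproducible across field realizations
  (with rough classes, the fourth-moment term of cluDiss is dominated by
  contrast noise and drowns the count signal);
* amplitudes are graded across pairs with the widest pair first, which
  anchors the patient-level rescale window of gradient cohorts.

`make_cohort()` assembles cohorts with controllable lesion counts,
heterogeneity (distinct classes/pairs per patient, or the number of
two-lobe lesions via `lobed_levels`), platinum-resistance probability
(logistic link on z-scored heterogeneity, intercept −1.2 ≈ 23% base
prevalence to mirror a 14/47 imbalance) and progression-free survival
(exponential hazard with log-linear link; exponential censoring at rate
λ·q/(1−q) yields censoring fraction q exactly under the base hazard). The
outcome-linked two-arm design used by the end-to-end check fixes four
lesions per patient and varies only whether lesions are internally
heterogeneous, so conventional measures (volume, site count) carry no
outcome information by construction and any classifier advantage must
come through the texture-heterogeneity channel. With lesion count held
fixed, the number of *distinct* texture classes is deliberately not used
as the outcome knob: duplicated subregions produce extreme bimodal GDM
cells that the fourth moment rewards, so that knob is non-monotone in
cluDiss — a genuine property of fourth-moment statistics worth knowing
when interpreting the measure.

# Problem sizes and numerical choices

The validation suite runs at deliberately modest scales chosen as
realistic desk-scale analogues: recovery checks use 50 replicates of
single-lesion phantoms (~800 voxels each); the monotonicity cohort is 40
patients with 2–8 two-lobe lesions of fixed 8 × 8 × 3-voxel radii; the
end-to-end cohort is 60 patients with the 100-repetition classifier
protocol. Tolerances: the compiled per-voxel GLCM maps agree with a naive
R re-computation to < 1e-10 (observed ~1e-14); geometry checks compare
spacing within 1e-4 mm and origin within 1e-3 mm; min–max ranges below
1e-9 relative width are treated as degenerate; zero-variance descriptor
channels are dropped from z-scoring rather than producing NaNs; kernel
K-means ties break toward the first cluster, and empty clusters are
re-seeded at the farthest point.

# Known limitations

* DICOM series are not read directly; convert to NIfTI first. One mask
  file per lesion is the native layout (a labelmap importer is provided)
  because lesion identity and site labels must survive independently.
* Volumes are analyzed on their native grid; no resampling to isotropic
  spacing is performed, and voxel spacing is carried in provenance.
* The published cut-offs do not transfer numerically (see above).
* cluDiss is a relative, cohort-internal measure here; absolute values
  depend on the GDM conventions and should be compared only within one
  configuration.
* Because of the per-patient min–max normalization, cluDiss is scale-free
  in the dissimilarity magnitudes: cohorts that differ *only* in how far
  apart their (otherwise internally homogeneous) lesions sit in texture
  space separate weakly. The measure's strength is the combined
  within-plus-between heterogeneity it was built for — phantom cohorts
  whose lesions are internally heterogeneous separate from homogeneous
  cohorts by an order of magnitude in median score.
* The phantom generator's scanner labels are metadata only; it does not
  simulate scanner-dependent feature shifts unless you inject them, which
  is exactly what the robustness-screen tests do.
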
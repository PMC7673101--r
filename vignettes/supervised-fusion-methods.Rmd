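---
title: "Reference-guided multimodal fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided multimodal fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Psychiatric cohorts are heterogeneous: patients sharing a diagnosis can
differ widely in symptom severity and in the brain systems involved.
`supfusion` implements a supervised fusion analysis for this setting. Two
voxelwise imaging features per subject — a functional one (fractional
amplitude of low-frequency fluctuations, fALFF) and a structural one
(gray-matter volume) — are decomposed *jointly*, with a clinical severity
score (such as the ADOS total) steering the decomposition toward
components whose subject weights track symptoms. The fitted patterns are
then carried to held-out groups (controls, other diagnostic subtypes, an
independent cohort) by linear projection, and their predictive value is
quantified by cross-cohort regression.

# The model

## Linear mixture per modality

Each modality $k$ is a subjects-by-voxels matrix modeled as a linear
mixture
$$X_k = A_k S_k,$$
where $S_k$ holds $M$ spatial component maps (rows) and $A_k$ the subject
loadings (columns). A subject's loading on a component is the quantity
tested against diagnosis and symptoms; the component's map, z-scored and
thresholded at $|Z| > 2$, defines its positive and negative networks.

## Reference-guided multiset CCA

After per-modality PCA whitening to $M$ dimensions (`pca_whiten()`),
`mccar()` finds one weight vector per modality and component maximizing

$$\sum_{k \ne j} \operatorname{corr}(A_k, A_j)^2
  + 2\lambda \sum_k \operatorname{corr}(A_k, \mathrm{ref})^2,$$

column-wise: the squared inter-modality correlation of the subject
loadings plus a reward, weighted by $\lambda \ge 0$, for correlating with
the clinical reference. With $\lambda = 0$ this is ordinary (unsupervised)
multiset CCA; the test suite checks the two-set case against a direct
generalized-eigenvalue oracle.

Implementation notes:

* For whitened inputs, each alternating update is an exact
  rank-restricted eigenproblem (a Rayleigh quotient over the stacked
  cross-correlation vectors), so the objective is non-decreasing within a
  component; the iteration log records it and a test asserts monotonicity.
* Components are extracted by deflation: later weight vectors are
  constrained orthogonal to earlier ones, which keeps each modality's
  loading columns mutually decorrelated.
* Each canonical column of modality $k > 1$ is sign-aligned to modality 1.
  The objective is sign-invariant, but the downstream joint ICA applies a
  *shared* unmixing matrix to all modalities; without a common
  orientation, components enter the concatenated maps with conflicting
  signs and separation collapses (we observed planted-source recovery
  dropping from $|r| \approx 1$ to $\approx 0.8$).
* Convergence is declared when the per-component objective changes by
  less than `tol = 1e-6` between sweeps. The objective is a sum of
  squared correlations of magnitude $O(1)$, so this resolves changes far
  below sampling noise; non-convergence at `max_iter` returns a result
  with a warning rather than an error, since near-degenerate noise
  components legitimately rotate freely.

## Joint Infomax ICA

`joint_ica()` concatenates the modality-wise canonical component maps and
runs natural-gradient Infomax ICA with a logistic nonlinearity — the
classical maximum-likelihood estimator for super-Gaussian sources — with
one unmixing matrix shared across modalities, so each joint component
keeps a single identity in both. Numerics:

* maps are row-centered and sphered before learning; learning uses
  randomized sample blocks under the run seed;
* the learning rate anneals by 2% only when successive weight updates
  disagree by more than 60°; annealing on any fluctuation freezes the
  weights prematurely and leaves sources mixed;
* divergence (non-finite or exploding weights) triggers a restart at half
  the learning rate, up to a retry cap;
* the returned sources unmix the *uncentered* maps, so
  `mixing %*% sources` reconstructs the input exactly — required for the
  back-reconstruction identity below;
* components are ordered by decreasing source variance, and `fuse()`
  flips each component so its modality-1 loading correlates
  non-negatively with the reference.

## Component selection

`select_reference_component()` correlates every component's loadings with
the reference in every modality, adjusts the $2M$ p-values by
Benjamini–Hochberg FDR, and — among components significant in *all*
modalities — picks the one with the largest minimum $|r|$ across
modalities, ties going to the lower index for determinism. Under a pure
noise model this selection stays non-significant in about 98% of runs at
$q = 0.05$ (checked by simulation), because the FDR correction counters
the optimism induced by the reference-guided optimization.

## Back-reconstruction and inference

`back_reconstruct()` estimates a new group's loadings as
$A_{new} = X_{new}\, S^{+}$, with $S^{+}$ the Moore–Penrose pseudo-inverse
(SVD, relative singular-value cutoff $10^{-10}$; a rank-deficient source
matrix is an error with a rank report). The generalized inverse is the
only sensible reading of "$S^{-1}$" for a non-square source matrix, and
it makes the operation exact whenever the new data lie in the row space
of $S$ — the property the tests assert with noise confined to the null
space.

Group differences on loadings use a two-sample t-test (pooled variance by
default, Welch available), optionally after residualizing covariates from
the loadings — the residualize-then-test reading of "covariates were
regressed out", chosen over ANCOVA because it mirrors how the feature
matrices themselves are adjusted. Clinical correlations are Pearson,
two-sided, via the t transform; partial correlations residualize both
vectors and reduce the degrees of freedom accordingly.

## Prediction and NRMSE

`fit_symptom_model()` fits
$\mathrm{score} = \beta_0 + \beta_1 f_{+} + \beta_2 f_{-} + \beta_3 s_{+}$
by OLS, where the three regressors are a subject's mean feature value
over the positive/negative functional networks and the positive
structural network of the selected component. The unweighted mask mean
(rather than a z-weighted sum) is used because three scalar summaries are
wanted and the mean is stable under rescaling; a weighted variant would
change nothing qualitative. Accuracy is reported as Pearson $r$ with its
p-value, RMSE, and NRMSE $= \mathrm{RMSE} / (y_{\max} - y_{\min})$ with
the range taken from the *observed true scores* of the evaluation set.

`cross_cohort_specificity()` applies every subtype's model (with its
masks) to every subtype's data in an independent cohort; the diagonal
cells measure generalization to the matched subtype, the off-diagonal
ones the (intended) failure to predict the other subtypes.

## Site stability

`leave_one_site_out()` drops one acquisition site at a time and re-runs
residualization, normalization, fusion and selection on the remainder.
Because ICA components have permutation and sign ambiguity, each run's
component is re-matched to an all-sites reference map by maximal spatial
$|r|$ and sign-aligned before thresholding; naive voxel tallies without
this step are meaningless. `occurrence_mask()` keeps voxels surviving
with the same sign in at least $\lceil f \cdot n_{runs} \rceil$ runs
(default $f = 0.70$). An absolute-count override is provided as well,
because "70% of sites" and "6 of 9 sites" are both common readings of a
stability rule and they differ at 9 sites ($\lceil 6.3 \rceil = 7$);
neither is silently chosen.

# fALFF and motion quality control

`compute_falff()` divides the sum of discrete-Fourier *amplitudes*
(moduli, not powers) over 0.01–0.08 Hz by the sum over the full
detectable band, capped at 0.25 Hz or the Nyquist frequency, whichever is
lower. The DC bin is excluded from both sums: the fALFF of a series
should not depend on its mean, and the full band is read as the
detectable *fluctuation* spectrum. Band edges are closed on the discrete
grid and configurable. The statistic is scale-invariant, lies in
$[0, 1]$, and an all-zero series returns 0 with a warning rather than
0/0. The tests pin the implementation to a brute-force DFT written
directly from the transform definition, to $10^{-10}$.

Framewise displacement is the Power-style sum of absolute backward
differences of the six rigid-body parameters, rotations converted to arc
length on a 50 mm sphere (configurable). QC fails a scan on mean FD
> 1 mm, any translation > 2 mm, or any rotation > 1°; defaults match
common practice and every threshold is an argument. Note the 0.25 Hz
denominator cap presumes TR = 2 s; for other TRs the cap is the Nyquist
frequency, which is the only defensible generalization when acquisitions
are mixed.

Gaussian smoothing uses a separable kernel with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel units and
reflective boundaries (constants are preserved exactly). Slice timing,
realignment and template warping are out of scope: inputs are assumed to
be on a common grid, as the synthetic data are.

# Feature matrices

`residualize_covariates()` removes age, full-scale IQ, handedness
(indicator columns for L and M against reference R) and acquisition site
($K-1$ indicators) per voxel by OLS. A site with a single subject makes
its indicator degenerate; it is merged into the largest site with a
warning (or rejected, per configuration). In the pipeline the
coefficients are fitted on the analysis (patient) group and applied to
controls, so the control adjustment never borrows patient-control
differences; this is configurable in the low-level API.
`normalize_ssq()` scales each modality by a single scalar to a common
mean square of 1 — only equality across modalities matters, and a unit
target keeps the reference weight $\lambda$ on an interpretable scale.

# What the synthetic generator emulates

`make_cohort()` produces a phenotype table (site, subtype, age,
handedness, IQ, ADOS subdomains and total, SRS, mean FD) with subdomain
scores drawn first and summed to the total, so subdomain-correlation
tests have ground truth. Controls carry no symptom scores. The paper
trail for ADOS subdomain distributions in public tables is thin, so the
families and their parameters are arguments with plausible defaults
(means near 4/6/2 with the clamping ranges of the instrument), not
fixed constants.

`make_multimodal_data()` draws $X_k = A_k S_k + E_k$ with Laplace
(super-Gaussian) sources and Gaussian noise. The reference component is
planted exactly: the patient loadings are built by Gram–Schmidt so their
empirical correlation with the ADOS total equals the target `ref_r`, and
patients receive a mean loading offset (`group_effect`, default 1 SD)
over controls, giving group-difference tests a known effect. Its source
map carries a shared positive "common" block in both modalities, and
each subtype listed in `unique_spec` adds one component whose modality-1
map is negative inside a disjoint subtype-specific block and whose
loadings follow the reference loadings inside that subtype only — so a
subtype-restricted fusion sees common-plus-unique as one component while
the whole-group fit can separate them.

Site offsets and linear age/IQ trends are injected through dedicated
*loading columns* rather than added to $X$ directly: this keeps the
generative identity $X = A S$ exact at zero noise (which the tests rely
on) while still giving covariate residualization real structure to
remove — a site offset times a source row is removed exactly by the site
indicators. `loading_noise_sd` optionally perturbs each modality's
loadings independently, weakening the cross-modal coupling; the
reference-guidance comparison is run in that regime (see below). A
`truth` argument re-draws subjects from an existing truth object,
emulating an independent cohort sampled from the same underlying
patterns — used by the cross-cohort projection and specificity analyses.

What the generator does **not** emulate: hemodynamics, scanner
artifacts, spatial autocorrelation, anatomically plausible geometry,
non-additive site effects, or missing data. Passing tests therefore
demonstrate the estimators' correctness and calibration under the stated
linear-mixture conditions, not robustness to everything real data can
do.

`make_fmri_timeseries()` builds 4D volumes whose voxel series are known
sinusoid mixtures plus white noise on a small grid (default
$12^3$), together with still / random-walk / spike motion traces — the
fixture for the fALFF and QC operators.

# Problem sizes and simulation settings

The test and acceptance harnesses run at desk scale, chosen so each
property is measured with adequate power:

* parameter recovery: 120 patients, 2000 voxels per modality, $M = 8$,
  planted loading-reference correlation 0.5, noise SD 0.25, 10–20 seeds;
* the reference-guidance contrast ($\lambda = 0.5$ vs $0$) runs at 60
  patients, 500 voxels, $M = 8$, half-strength reference source, noise
  SD 1.5 and loading noise SD 1. Supervision matters precisely when the
  target covariation is weak and imperfectly coupled across modalities —
  with strong, perfectly coupled components the unsupervised fit already
  recovers the component and the contrast is a tie;
* null calibration: 50 pure-noise fusions (60 subjects, 300 voxels,
  $M = 5$) for the selection rate; 500 uniform-null replicates at
  $m = 100$ for BH;
* site stability: 9 balanced sites, 135 patients, 500 voxels, $M = 6$.

$M$ defaults to 30 in `fusion_config()` for real-data-scale analyses;
the synthetic studies use small $M$ matching their planted rank.

# Open design points, resolved

* **$\lambda$** is nowhere pinned by the method's sources; the default is
  0.5, it is never applied silently (every result object records it),
  and the guidance contrast above is the package's own check that the
  term does what it claims.
* **Which column the reference term binds to** is left free: the
  objective rewards reference correlation wherever it appears, and the
  selection step identifies the reference component afterwards.
* **FDR families**: clinical correlations are adjusted within each
  modality's subdomain family; the selection step adjusts across the
  full $2M$ component-by-modality family. `fdr_adjust()` rejects at
  adjusted $p \le q$ (the classical step-up rule); the selection step
  uses strict `<` as its contract states.
* **"Common" networks** across subtypes are operationalized as the
  intersection of the subtypes' thresholded masks and "unique" as the
  set difference against the union of the others — an explicit
  formalization of a comparison that is often made visually; the
  partition property (common disjoint from every unique mask) is tested.

# Known limitations

* Two modalities are assumed by the pipeline wrappers (the MCCA and ICA
  cores accept any number of sets); N-way fusion is out of scope.
* No ICASSO-style stability ranking or data-driven estimation of $M$.
* Linear covariate adjustment only; no empirical-Bayes harmonization.
* The Infomax nonlinearity targets super-Gaussian sources, which imaging
  component maps (sparse networks) are; sub-Gaussian sources would need
  the extended variant, which is not implemented.
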
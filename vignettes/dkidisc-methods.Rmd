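---
title: "Methods: two-shell kurtosis imaging and cohort discrimination in dkidisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-shell kurtosis imaging and cohort discrimination in dkidisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkidisc)
```

## The signal model

Diffusional kurtosis imaging extends the Gaussian diffusion-tensor model
with a fully symmetric rank-4 kurtosis tensor $W$ that captures
non-Gaussian water diffusion. Along a unit direction $n$ at b-value $b$,

$$S(b, n) = S_0 \exp\!\left(-b\,D_{app}(n) +
  \tfrac{1}{6} b^2 D_{app}(n)^2 K_{app}(n)\right),$$

with $D_{app}(n) = \sum_{ij} n_i n_j D_{ij}$ and
$K_{app}(n) = (\overline{D}^2 / D_{app}^2) \sum_{ijkl} n_i n_j n_k n_l
W_{ijkl}$, where $\overline{D}$ is the mean diffusivity. The model has 22
parameters per voxel: $\log S_0$, six unique components of $D$, and fifteen
unique components of $W$. A single non-zero shell cannot separate the $b$
and $b^2$ terms, so a two-shell acquisition is the minimal identifiable
protocol; the package default is 30 directions at
$b \in \{1000, 2000\}\ \mathrm{s/mm^2}$ plus five $b = 0$ volumes (65
volumes), with the same deterministic electrostatic-repulsion direction set
reused on both shells. Diffusivities are carried in
$\mu\mathrm{m}^2/\mathrm{ms}$ ($= 10^{-3}\,\mathrm{mm^2/s}$), the scale on
which regional values are conventionally tabulated; b-values are stored in
$\mathrm{s/mm^2}$ and rescaled internally.

## Fitting: initialisation, refinement, constraints

`fit_dki_voxel()` proceeds in three stages.

1. **Weighted linear initialisation.** The log-signal model is linear in
   the 22 parameters. Ordinary least squares on log-signals is followed by
   two reweighting passes with weights equal to the squared predicted
   signal, the standard compensation for log-domain heteroscedasticity.
2. **Levenberg–Marquardt refinement.** The signal-domain model
   $S = \exp(X\beta)$ is refined by Levenberg–Marquardt with an analytic
   Jacobian. If the refinement fails to reduce the residual it is discarded
   in favour of the linear solution and flagged; by construction the
   reported residual never exceeds the initialisation residual.
3. **Constraint projection.** Eigenvalues of $D$ are clamped to be
   non-negative, and $K_{app}$ on the acquisition directions is confined to
   $[K_{min},\ 3/(b_{max} D_{app})]$ — the upper limit is where the
   truncated cumulant expansion stops being monotone in $b$. The projection
   minimises the change of apparent kurtosis (a quadratic program solved by
   Hildreth dual coordinate ascent in the $K_{app}$ metric), with a
   guaranteed-feasible fallback that shrinks $W$ toward zero. Activated
   constraints are reported in the fit diagnostics.

**The lower kurtosis bound.** We default $K_{min} = -3/7$, the conventional
minimum apparent kurtosis, rather than zero. A hard zero floor truncates
the sampling distribution of $K_{app}$ for kurtosis-free tissue and biases
its mean kurtosis upward by roughly $+0.1$ at SNR 50 under this protocol,
an order of magnitude larger than the estimator's statistical error; the
$-3/7$ bound retains the protection against degenerate fits while leaving
the estimator essentially unbiased at the Gaussian limit. The bound is a
configuration field (`dki_fit_config(k_min = ...)`) for users who want the
stricter convention.

**Magnitude-MRI noise floor.** Magnitude images carry Rician noise: at low
signal the measured magnitude is biased upward, which masquerades as extra
kurtosis at high b. The fitter compensates by the method of moments
($E[M^2] = S^2 + 2\sigma^2$): a first pass estimates $\sigma$ from the fit
residuals (or accepts a known `noise_sigma`), signals are corrected as
$\sqrt{\max(M^2 - 2\hat\sigma^2, 0)}$ — floored at $0.2\hat\sigma$ so the
log-domain initialisation stays bounded where the measurement is pure
noise — and the model is refit. Noiseless input is a fixed point of the
whole procedure.

**Second-order kurtosis bias.** $K_{app}$ is the ratio $A/B^2$ of two
estimated quantities whose errors are correlated through the shared design
(an overestimated diffusivity must be compensated by an overestimated
curvature term). The plug-in ratio therefore has an $O(\sigma^2)$ bias —
about $-0.05$ in mean kurtosis at SNR 50 for this protocol, and
independent of the weighting scheme. `compute_metrics()` removes the
leading term with a delta-method correction built from the fit's parameter
covariance, applied only where the expansion is trustworthy (relative SD
of $D_{app}$ below 20%) and capped at $\pm 1$. With both corrections the
mean fitted MK of kurtosis-free voxels at SNR 50 sits within $\pm 0.01$ of
zero.

## The eight scalar metrics

From the eigen-system $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of $D$:
MD $= \bar\lambda$, $D_{axial} = \lambda_1$,
$D_{radial} = (\lambda_2 + \lambda_3)/2$, and FA is the usual normalised
eigenvalue dispersion. Kurtosis metrics are directional averages of
$K_{app}$: **MK** over the 30 acquisition directions (matching the
derive-and-average convention of two-shell protocols; a dense 256-direction
option is provided and agrees within 0.02 for smooth $W$ — tested),
**K_axial** along $e_1$, and **K_radial** over 64 equally spaced azimuths
perpendicular to $e_1$ (64 azimuths approximate the analytic perpendicular
average far below metric noise). **KFA** is the Frobenius-norm anisotropy
$\|W - \bar{W} I^{(4)}\|_F / \|W\|_F$ with
$\bar W = (W_{1111} + W_{2222} + W_{3333} + 2W_{1122} + 2W_{1133} +
2W_{2233})/5$, set to zero for vanishing $W$. All eight metrics are
invariant under joint rotation of tensors and directions to $10^{-10}$
(property-tested).

## Denoising

`denoise_local_pca()` implements sliding-window local PCA with
Marchenko–Pastur noise-bulk detection: per cubic patch (default radius 2,
i.e. $5^3 = 125$ voxels), the mean-centred patch matrix is
eigen-decomposed and the largest lower tail of the spectrum consistent
with a pure-noise bulk is suppressed; overlapping patches are averaged.
Exactly low-rank input is a fixed point, and patch means are preserved, so
homogeneous-region signal levels are untouched (both tested). The patch
radius and the automatic $\sigma$ estimator are our defaults — reasonable
standard choices, not claimed to replicate any particular external
pipeline's settings.

## Phantoms and ground truth

`phantom_spec()`/`simulate_dwi()` build labelled tensor-field phantoms:
white matter (prolate $D$, MK 0.9), thalamus-like deep gray (MK 0.85), and
CSF ($D = 3.0$ isotropic, $W = 0$), with 15% of white-matter voxels
converted to hyperintensity lesions (raised diffusivity, MK 0.6) and the
CSF block doubling as the ventricle mask. Ground-truth kurtosis tensors are
generated as Gaussian-compartment mixtures — their kurtosis tensor is a
symmetrised covariance of compartment tensors, so apparent kurtosis is
non-negative in every direction by construction — then rescaled to the
target MK. Noise is Rician (magnitude of a complex Gaussian perturbation),
with SNR defined on the b0 signal. Phantoms whose predicted signal would
*increase* with b anywhere (kurtosis beyond the validity range at
$b_{max}$) are rejected at simulation time.

Because compartments are piecewise constant, local PCA denoising is close
to ideal on these phantoms; real tissue has gradients, partial-volume
mixtures and anatomy-correlated noise that the generator deliberately does
not emulate. Pipeline accuracy figures on phantoms are therefore upper
bounds on real-data performance, and the voxelwise (undenoised) figures
are the conservative complement.

## The synthetic cohort

`generate_cohort()` draws 42 / 50 / 30 subjects (the three-group design:
vascular-disease, Alzheimer's-type and cognitively normal) with one feature
column per region, hemisphere and metric (16 white-matter tracts + 14
thalamic nuclei, times eight metrics). Group means and SDs per compartment
and metric, and all covariate distributions (age, education, symptom
duration, lesion-rating scale, lesion volume, lacune count, ischemic
score, cognition scores, sex and dementia-stage frequencies), are
calibrated to the published summary tables of the three-group comparison
this package models. Within a subject, features are equicorrelated at
$\rho = 0.3$ via a shared latent factor — exact for an exchangeable
correlation structure; the marginals are all the source tables provide, so
the correlation level is our modelling choice, fixed once. Covariates are
truncated to valid ranges (non-negative volumes, counts and durations;
cognition scores clipped to their scales) and lacune counts are rounded.

One calibration value needed a judgement call: the tabulated SD of
white-matter mean kurtosis in the Alzheimer's-type group prints as .606,
two orders of magnitude out of line with every neighbouring SD (.02–.13)
and incompatible with the reported significance pattern. We treat it as a
decimal-point typo and use 0.0606, preserving the printed value in the
calibration table's `printed_sd` column rather than silently normalising
it.

The generator does **not** model feature–covariate correlations (e.g.
lesion volume does not co-vary with kurtosis within group), longitudinal
structure, or site effects. Consequences: covariate-adjusted group tests
on synthetic cohorts lose only degrees of freedom to the adjustment, and
detection rates here speak to the calibrated effect sizes, not to
confounding robustness.

## Statistics

* **Demographics** — one-way ANOVA for continuous variables, chi-square
  for categorical, Tukey flags for pairwise contrasts.
* **Adjusted group comparisons** — `ancova_tukey()` fits the additive
  model `feature ~ group + covariates` (age, education, symptom duration,
  lesion volume, lacune count by default), tests the group term by
  extra-sum-of-squares F (identical to the Type III test in a
  main-effects model), and compares covariate-adjusted means with Tukey's
  studentized-range correction using model-based standard errors. With no
  covariates this reduces *exactly* to ANOVA + Tukey HSD (tested).
  Pairwise flags follow the a / b / c convention (SIVD–AD, SIVD–NC,
  AD–NC). Multiple testing across regions is deliberately not corrected
  by default, matching the analysis convention this package mirrors; a
  Benjamini–Hochberg pass can be applied by the user via `p.adjust`.
* **Constraints** — `apply_constraint()` subsets to early or low-burden
  disease: CDR ≤ 0.5 (normal controls without a CDR value count as 0),
  lesion volume ≤ 15 ml, lacunes ≤ 8. The threshold comparison for lesion
  probability maps is ≥ 0.5 (configurable strictness).
* **Discriminant classification** — pooled-covariance linear discriminant
  analysis with proportional priors and a Moore–Penrose pseudo-inverse, so
  duplicated or collinear features degrade gracefully. The headline figure
  is the resubstitution correct-classification rate (the
  original-grouped-cases convention of classical statistics packages);
  leave-one-out is reported alongside on request. A brute-force
  discriminant-score oracle and a reference LDA implementation both verify
  the rule in the test suite.
* **ROC** — binary logistic scores (ridge fallback under perfect
  separation, flagged), AUC as Mann–Whitney concordance with ties counting
  one half, oriented toward the target class, Hanley–McNeil
  distribution-free 95% CI (stratified bootstrap optional). The rank AUC
  equals the trapezoidal area under the empirical curve (tested), and a
  reference ROC package cross-checks the value.
* **Stepwise regression** — Pearson screen at $p < 0.05$, iterative
  removal of variance inflation factors ≥ 5 (highest first; order-stable),
  then forward–backward p-value stepwise OLS with the adjustment
  covariates forced in (entry 0.05 / removal 0.10 — common defaults, fixed
  here as configuration).

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes are chosen as the smallest
that make the statistical assertions stable: 1000 noiseless voxels for the
round trip, 400–500 voxels per noise condition, a 12×12×15 phantom
(≈ 600 usable white-matter voxels) for pipeline accuracy, 10,000
replicates for the null-calibration of the adjusted group test, 200 seeds
for null stepwise selection, and 50 cohort seeds for the end-to-end
trends. Degenerate inputs are handled without exceptions wherever a value
can still be defined: background voxels are flagged invalid, fully
excluded regions yield missing values that propagate as such, an empty
stepwise screen returns an empty selection, and constraint-emptied groups
warn while the remaining groups stay usable.

## Known limitations

Phantoms are piecewise constant (no partial volume, no anatomy);
simulated cohorts have exchangeable feature correlation and
group-independent covariates; the discriminant headline rate is
resubstitution-based and optimistic for small samples (leave-one-out is
the honest companion figure); logistic ROC on many features with modest
samples overfits toward AUC 1 — the per-contrast AUCs on regional feature
blocks should be read as in-sample discrimination, as in the analysis
convention this package reproduces.
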
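# dkidisc

Diffusional kurtosis imaging (DKI) simulation, constrained model fitting,
and cohort discrimination statistics for the ageing spectrum — subcortical
ischemic vascular disease (SIVD), Alzheimer's disease (AD), and cognitively
normal (NC) older adults.

Identifying early-stage SIVD is hard: the macroscopic hallmarks (white
matter hyperintensities, lacunes) also occur in AD and in healthy ageing.
Diffusional kurtosis metrics of normal-appearing white matter and of the
thalamus are sensitive to the underlying microstructural pathology before
the macroscopic burden evolves. `dkidisc` provides an end-to-end, fully
synthetic test bed for that analysis chain:

* **Acquisition & phantoms** — deterministic two-shell gradient schemes
  (30 directions, b = 1000/2000 s/mm², 5 b0 → 65 volumes), labelled
  tensor-field phantoms with Rician noise and lesion/ventricle masks, and a
  synthetic cohort generator calibrated to published three-group summary
  statistics (n = 42/50/30).
* **Reconstruction** — local-PCA (Marchenko–Pastur) denoising; voxelwise
  DKI fits by weighted linear initialisation + Levenberg–Marquardt
  refinement with constraint projection, Rician floor compensation and a
  second-order kurtosis bias correction; the eight scalar metrics
  (MD, D_axial, D_radial, FA; MK, K_axial, K_radial, KFA).
* **Regional statistics** — lesion-probability thresholding (≥ 0.5),
  atlas means over 16 white-matter tracts and 14 thalamic nuclei with
  lesion/ventricle voxel exclusion and full bookkeeping.
* **Cohort inference** — covariate-adjusted group comparisons (ANCOVA +
  Tukey), clinical-constraint subsetting (CDR ≤ 0.5, WMH ≤ 15 ml,
  lacunes ≤ 8), pooled-covariance linear discriminant classification,
  logistic-probability ROC with Hanley–McNeil intervals, and
  correlation-screened VIF-pruned stepwise regression.

The voxel model is
`S(b, n) = S0 exp(−b D_app(n) + b² D_app(n)² K_app(n) / 6)`, with
`D_app(n) = nᵀ D n` and `K_app(n) = (MD²/D_app²) Σ nᵢnⱼnₖnₗ W_ijkl`
— 22 parameters per voxel (log S0, 6 diffusion-tensor, 15 kurtosis-tensor
components). See the methods vignette
(`vignettes/dkidisc-methods.Rmd`) for the estimator, the constraint set,
and the synthetic-cohort calibration.

## Worked example

```r
library(dkidisc)
set.seed(7)

## acquisition scheme and a noisy phantom
scheme <- build_scheme(30, c(1000, 2000), 5)
scheme
#> Gradient scheme: 65 volumes ( 5 b0 + 30 directions x 2 shells: b = 1000, 2000 s/mm^2 )

ph  <- phantom_spec(grid = c(10, 10, 10), snr = 25, seed = 7)
sim <- simulate_dwi(ph, scheme)
dwi <- denoise_local_pca(sim$dwi)
wm  <- sim$labels == 1
fit <- fit_volume(dwi, scheme, wm)
mean(fit$metrics$MK[wm], na.rm = TRUE)   # 0.880 (ground truth 0.853:
                                         # normal WM MK 0.9, lesions 0.6)

## calibrated synthetic cohort and the inference chain
co    <- generate_cohort(cohort_spec(seed = 7))   # 122 subjects, 42/50/30
wm_mk <- compartment_average(co, "MK", "WM")
a     <- ancova_tukey(co, wm_mk)   # adjusted for age, education, duration,
                                   # WMH volume, lacunes
a$pairwise
#>       contrast label  estimate            p significant
#>     SIVD vs AD     a   -0.0926 2.4e-11             TRUE
#>     SIVD vs NC     b   -0.1620 4.6e-14             TRUE
#>       AD vs NC     c   -0.0694 1.5e-05             TRUE

discriminant_classify(co, feature_columns(co, c("MK", "K_radial", "FA"), "WM"))
#> Linear discriminant analysis over 48 features:
#>   correct classification: 88.5% (resubstitution)
#>       predicted
#> truth  SIVD AD NC
#>   SIVD   37  5  0
#>   AD      2 44  4
#>   NC      0  3 27

roc_from_logistic(co, feature_columns(co, "MK", "WM"), c("SIVD", "NC"))
#> ROC SIVD vs NC: AUC = 1.000 (95% CI 1.000-1.000), n = 42/30
```

The ANCOVA flags (a/b/c = SIVD–AD / SIVD–NC / AD–NC) say which adjusted
pairwise contrasts are significant; the discriminant confusion matrix rows
are true groups; the AUC is in-sample discrimination of the logistic
probability scores (regional feature blocks separate these calibrated
groups essentially perfectly for the SIVD-vs-NC contrast).

A command-line wrapper for the same pipeline (simulate / make-cohort /
fit / extract / analyze) ships in `inst/cli/dkidisc-cli.R`.

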
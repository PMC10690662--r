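# sipcom

Detection of focal cortical hypometabolism on interictal [18F]FDG-PET by
subtraction of a pseudo-normal PET predicted from the patient's own
T1-weighted MRI.

In presurgical work-up of drug-resistant focal epilepsy, interictal FDG-PET
hypometabolism marks dysfunctional epileptic cortex, but voxel-wise
comparison against a control database (statistical parametric mapping)
requires heavy spatial normalization and smoothing. This package implements
the personalized alternative: a 3D conditional adversarial network
(pix2pix-style, U-Net generator with residual units) trained on healthy
controls learns the T1w → FDG-PET mapping, so a patient's MRI can be
translated into the PET they would have under normal metabolism. The
anomaly map is then

```
Z_i = -( D_i − μ_D ) / σ_D ,   D = PET_clinical − r · PET_predicted ,
r = mean_mask(PET_clinical) / mean_mask(PET_predicted)
```

with μ, σ taken within the brain mask (population SD; the sign flip makes
hypometabolism positive), thresholded at Z > 2.33 within the mask eroded by
three voxels, keeping 26-connected clusters of at least 1 mL (1000 voxels at
1 mm³). Detected clusters are localized against 18 bilateral cortical
regions and scored by concordance with the surgical resection zone.

The package is audience-complete for method development without any data
download: it ships a paired T1w/PET phantom simulator with injectable
hypometabolic lesions and a toy 36-label atlas, masked image-quality metrics
(MAE, PSNR, SSIM), the full cluster/Z-map machinery, a per-patient cohort
table for the evaluation statistics, and a neural-network engine (3D
convolutions, transpose convolutions, batch norm, PReLU, Adam, reverse-mode
gradients) written in vectorized base R — no deep-learning framework
dependency.

## Worked example

Simulate a subject with a 2 mL lesion at 70% intensity, use the
ground-truth lesion-free PET as the oracle predictor, and run the
subtraction pipeline:

```r
library(sipcom)

axes  <- c(26, 28, 24)                               # ellipsoid semi-axes, mm
study  <- generate_phantom(phantom_spec(shape = rep(64, 3), voxel_mm = 1,
                                        semi_axes_mm = axes, noise_sd = 0.02,
                                        fwhm_mm = 3, seed = 42))
normal <- generate_phantom(phantom_spec(shape = rep(64, 3), voxel_mm = 1,
                                        semi_axes_mm = axes, noise_sd = 0,
                                        fwhm_mm = 3, seed = 42))
lesion   <- lesion_spec(center_mm = c(12, 8, 0), radius_mm = 7.8, factor = 0.7)
clinical <- inject_lesion(study$pet, lesion, study$mask)

res <- run_sipcom(clinical, study$mask, predicted = normal$pet,
                  atlas = study$atlas, atlas_table = study$atlas_table)
res
#> <sipcom_result>
#> <sipcom_zmap> 64x64x64; mu=5.01e-17 sigma=0.03633, hypometabolism-positive convention
#> <sipcom_clusters> 1 cluster(s)
#>   cluster_id n_voxels volume_ml peak_z mean_z centroid_i centroid_j centroid_k
#> 1          1     2125     2.125  7.949  5.428      44.73      40.65      32.51
#>   centroid_x_mm centroid_y_mm centroid_z_mm               regions
#> 1         12.23         8.148      0.005882 PMT_R + ATL_R + PLT_R
#>       overlap_fractions
#> 1 0.566 + 0.413 + 0.021
```

Exactly one cluster survives the extent rule: 2.125 mL (the injected lesion
was 2 mL), peak Z ≈ 7.9, centroid within 0.3 mm of the injected centre
(12, 8, 0), assigned to the right-hemisphere toy-atlas sectors it straddles.

Cohort-level scoring of the packaged per-patient table:

```r
evaluate_cohort()
#> <sipcom_evaluation> 20 patients
#>         group method count  n  rate percent
#>           all sipcom    12 20 0.600    60.0
#>           all    spm     7 20 0.350    35.0
#>           all visual    17 20 0.850    85.0
#>    engel_good sipcom     9 14 0.643    64.3
#>    engel_good    spm     5 14 0.357    35.7
#>  ...
#>  mri_negative sipcom     4  8 0.500    50.0
#>  mri_negative    spm     1  8 0.125    12.5
#>  mri_negative visual     5  8 0.625    62.5
```

The subtraction method localizes the resection zone in 60% of patients
versus 35% for the voxel-wise mapping comparator and 85% for expert visual
reading, with the same ordering in the Engel-outcome and MRI-status
subgroups.

Training the translation model at toy scale (CPU-friendly; the full-scale
configuration is `gan_config(profile = "full")`):

```r
prep <- function(st) { st$t1w <- minmax_scale(st$t1w)
                       st$pet <- minmax_scale(gaussian_smooth(st$pet, 2)); st }
pairs <- lapply(1:4, function(s) prep(generate_phantom(
  phantom_spec(semi_axes_mm = c(46, 56, 46) + 2 * s, noise_sd = 0,
               fwhm_mm = 3, seed = s))))
state <- train_gan(pairs, gan_config(profile = "toy", epochs = 50, seed = 7))
pred  <- predict_volume(state, pairs[[1]]$t1w)
```

A command-line front end covering `simulate`, `train`, `predict`, `sipcom`,
`metrics` and `evaluate` is installed at `inst/cli/sipcom.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/sipcom.R", package="sipcom"))') help`).

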
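---
title: "Pseudo-normal PET subtraction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-normal PET subtraction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipcom)
```

## The problem and the method

Interictal [18F]FDG-PET of patients with drug-resistant focal epilepsy shows
focal hypometabolism in dysfunctional epileptic cortex, but reading it
reliably is hard. The approach implemented here compares each patient against
*themselves*: a conditional adversarial network trained on healthy controls
learns the mapping from T1-weighted MRI to FDG-PET, so a patient's own MRI
can be translated into the PET they *would* have if their metabolism were
normal. Subtracting this pseudo-normal prediction from the clinical PET and
standardizing the difference yields a Z-map whose supra-threshold clusters
mark candidate hypometabolic foci. Cohort-level performance is scored by
region-wise concordance of the detected clusters with the surgically resected
cortex (the available surrogate for the epileptogenic zone), using 18
bilateral cortical labels.

The pipeline stages, each exposed as a function:

1. **Preprocessing** (`gaussian_smooth`, `minmax_scale`): volumes are assumed
   already co-registered on a common lattice; the PET is smoothed with a 2 mm
   Gaussian kernel and all volumes are min-max scaled to [0, 1].
2. **Translation model** (`train_gan`, `predict_volume`): a 3D patch-based
   pix2pix-style model; details below.
3. **Anomaly map** (`scale_predicted`, `difference_zmap`): the predicted PET
   is multiplied by the ratio of in-mask mean intensities (clinical /
   predicted) so global scaling cannot masquerade as pathology; the
   difference is converted to Z-scores with the mean and population SD taken
   within the brain mask.
4. **Cluster detection** (`extract_clusters`): voxels with Z above 2.33
   inside the brain mask eroded by three voxels are grouped by 26-connectivity;
   components smaller than 1 mL (1000 voxels at 1 mm isotropic — the rule is
   stated in mL and converted through the voxel volume, so it generalizes to
   other grids) are discarded.
5. **Evaluation** (`cohort_rates`, `region_recall_precision`,
   `score_control_fp`): patient-level concordance is a non-empty intersection
   between the method's region set and the resection-zone region set.

## The translation model

The generator is a 3D U-Net: five encoder stages with 32, 64, 128, 256 and
512 channels (downsampling by stride-2 convolutions), a mirrored decoder
(upsampling by stride-2 transpose convolutions), one residual unit per stage,
skip concatenation, PReLU activations and batch normalization, and a sigmoid
output matching the [0, 1] intensity range. The discriminator is a
conditional PatchGAN scoring concatenated (T1w, PET) patches through stride-2
convolutions with 64, 128, 256, 512 and 1 channels. Training draws 32^3
voxel patches whose centres lie inside the brain mask, and alternates Adam
updates (constant learning rate 2e-4, betas 0.5/0.999) of

* the generator, minimizing ½(λ·MSE + adversarial loss) with λ = 200, and
* the discriminator, minimizing ½(real term + fake term),

with binary cross-entropy on the discriminator score maps as the adversarial
form (a least-squares option is available). Two published sentences describe
"the generator" loss; we read the second ("adversarial loss divided by two")
as the discriminator's, mirroring the pix2pix convention the architecture
derives from. Where the published description is silent we chose: one
residual unit per stage; kernel-2/stride-2 transpose convolutions; patch
sampling density exposed as `patches_per_volume`; batch-norm inference with
running statistics (eval mode).

The engine itself — 3D convolution, transpose convolution, batch
normalization, PReLU, Adam, and reverse-mode gradients — is implemented
in-package in vectorized base R: convolutions are evaluated tap-by-tap as
row gathers followed by BLAS matrix products, and the backward pass is
expressed as a transposed gather so no scatter-add is needed. Correctness is
pinned by finite-difference gradient checks in the test suite.

Whole-volume prediction tiles the T1w with 50%-overlapping windows,
reflect-padded to a whole number of windows, blended with Hann (cosine-taper)
weights and normalized by the accumulated weight so the weights sum to one at
every voxel; a patch-wise identity therefore reproduces the input exactly.

## The synthetic phantom

`generate_phantom` builds paired T1w/PET volumes from a shared geometry: an
ellipsoidal brain with three concentric shells (WM core, GM band, CSF rim)
whose normalized-radius boundaries sit at 0.55 and 0.85. Each tissue class
has a mean T1w and PET intensity in [0, 1] (defaults: GM brightest on PET at
0.80, WM brightest on T1w at 0.85), Gaussian noise of SD 0.02 is added
*before* Gaussian smoothing (default FWHM 3 mm) so the noise is spatially
correlated, as PSF-limited PET noise is. The default grid is 64^3 voxels at
2 mm; the lesion-recovery experiments use 64^3 at 1 mm with semi-axes
26/28/24 mm so a 2 mL lesion and the 3-voxel mask erosion both fit
comfortably. A toy atlas of 36 labels (18 regions x 2 hemispheres, by
hemisphere sign, three axial slabs and six angular wedges) exercises all the
label bookkeeping without pretending to anatomy. `inject_lesion` multiplies
PET intensity inside a sphere by a factor in (0, 1], with optional Gaussian
edge feathering, leaving all other voxels bit-identical.

What the phantom does *not* emulate: cortical folding, partial-volume
effects, scanner physics, registration error, inter-subject anatomical
variability beyond ellipsoid semi-axes, and pathology other than focal
multiplicative hypometabolism. Passing phantom tests therefore demonstrates
the correctness of the machinery (standardization, clustering, stitching,
bookkeeping) and a genuine learning signal — not clinical-grade synthesis
quality on real brains.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| PET smoothing FWHM | 2 | mm | published preprocessing; "2 mm Gaussian" read as FWHM (the neuroimaging convention), σ = FWHM/2.3548 |
| Z threshold | 2.33 | – | one-sided p ≈ 0.01 |
| Minimum cluster volume | 1 | mL | extent rule; 1000 voxels at 1 mm³ |
| Mask erosion | 3 | voxels | suppresses low-intensity border artifacts |
| Cluster connectivity | 26 | – | common for cluster analysis; configurable 6/18/26 |
| Erosion structuring element | 6-connected | – | face-adjacency cross, iterated; configurable to 26 |
| λ (MSE weight) | 200 | – | published loss weight |
| Learning rate | 2e-4 | – | published, constant |
| Patch edge | 32 | voxels | published patch size |
| SSIM window / constants | 7³, K1 = 0.01, K2 = 0.03 | – | field-standard SSIM parameters |

## Numerical and convention choices

* **Sign convention.** The difference is clinical − predicted, yet the
  stated detection rule thresholds *positive* Z while seeking
  *hypo*metabolism; by default the standardized map is negated
  (hypometabolism-positive) so the published threshold is operative for its
  stated target. A flag restores the raw tail.
* **σ is the population (n-denominator) SD**, the usual Z-score convention
  over a complete voxel population.
* **Degenerate standardization.** A difference image with zero in-mask
  variance (e.g. predicted identical to clinical, or offset by a constant)
  has no meaningful Z-map and is rejected with an informative error rather
  than silently returning zeros.
* **Smoothing** uses separable kernels scaled per-axis by the voxel size,
  with replicate padding so constant volumes are preserved exactly; the
  kernel is truncated at 4σ.
* **Min-max scaling** uses the whole volume by default (no mask restriction
  is stated for the published preprocessing); a mask-restricted domain is
  available. Smoothing is applied before scaling by default; the order is
  configurable because the published order is unstated.
* **Mean-ratio scaling** computes both means within the brain mask, so
  background voxels cannot dominate the ratio.
* **SSIM masking.** The published evaluation masked the predicted PET before
  computing metrics but does not say whether averaging was mask-restricted;
  the default computes on masked-to-zero volumes and averages windows whose
  centres are in-mask, avoiding background inflating similarity; a
  whole-volume mode is provided. MAE and PSNR are mask-restricted.
* **Cluster counts are not monotone in the Z threshold**: raising the
  threshold can split one cluster into several. What is monotone — and what
  the tests assert — is containment (every higher-threshold cluster lies
  inside a lower-threshold one), total supra-threshold volume, and the count
  under the minimum-volume rule.
* **Connected components** are labelled through an adjacency edge list and
  graph components (igraph); the test suite checks equivalence against an
  independent brute-force flood fill at all three connectivities on
  randomized volumes.

## Cohort table and scoring

The packaged per-patient table (20 operated patients) transcribes the
published cohort: Engel outcome class (I–II good, III–IV poor), MRI status,
lobar localisation, and the region sets of SEEG, surgery, visual reading,
SPM and the subtraction method, in a compact dialect ("AML + ATL R") in
which a hemisphere letter distributes over the preceding run of codes. The
resection zone is the surgery column, with "Idem" resolving to the SEEG set.
Patient-level detection rates over this table are exact integer ratios and
reproduce the published rates. Region-level recall and precision are
micro-averaged (summed intersection sizes over summed set sizes); the
published recall/precision values follow a definition that is not spelled
out and could not be reconstructed from the table under any obvious
candidate, so they are documented but not asserted — the packaged values are
regression-tested against an independent hand tally instead. Lobe-level
(temporal vs extra-temporal) subgrouping is available as a generic predicate
filter; the published temporal-lobe subgroup counts cannot be reconciled
with the table under a single assignment of the temporo-parieto-occipital
junction patients and are likewise not asserted.

## Problem sizes used by the packaged experiments

The test suite and the acceptance script run scaled-down, CPU-friendly
analogues of the full-scale experiments, chosen once as realistic for
phantom work: lesion recovery uses 20 phantoms of 64^3 voxels at 1 mm with
one 2 mL lesion at intensity factor 0.7 (detection: Z > 2.33, ≥ 1 mL,
3-voxel erosion); the learning-signal check trains the toy configuration
(8/16/32 generator channels, 16^3 patches, 8 patches per volume per epoch,
batch 4, learning rate 2e-3, 50 epochs) on four noiseless phantoms and
evaluates masked SSIM and MAE on a held-out phantom against the untrained
network. The full-scale published configuration (32–512 channels, 32^3
patches, 1000 epochs, batch 20, 37 real controls) is expressible with
`gan_config(profile = "full")` but is a GPU-scale computation; its
published image-quality values (MAE 0.0042, PSNR 35.14, SSIM 0.991 on real
controls) are not reproducible from phantoms and are not asserted anywhere
in this package.

## Known limitations

* The phantom's tissue-lookup mapping is far easier to learn than real
  MRI-to-PET translation; toy-scale SSIM says nothing quantitative about
  real-data synthesis quality.
* Registration, bias correction and skull stripping are out of scope: inputs
  must already be co-registered on a common lattice with a brain mask.
* The voxel-wise statistical-mapping comparator is represented only by its
  published per-patient region sets in the cohort table; the comparator
  analysis itself is an external tool and is not reimplemented.
* Training on a single CPU in base R is practical only at toy scale; the
  engine is exact but not fast.
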
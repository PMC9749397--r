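---
title: "Synthetic-baseline FDG-PET: model, normalization and abnormality mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-baseline FDG-PET: model, normalization and abnormality mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpet)
```

## The problem

Clinical FDG-PET reading in suspected dementia usually compares a patient's
uptake against a statistical template built from other people's brains.
When the patient's anatomy deviates from the template population — enlarged
ventricles, cortical thinning, idiosyncratic morphology — the comparison
flags *anatomical* difference as *metabolic* abnormality. `sbpet`
implements the alternative: synthesize a healthy-appearing FDG-PET volume
(an "sbPET") from the patient's **own** T1-weighted MRI with a conditional
adversarial model, and read abnormality as the voxel-wise relative
deviation of the measured PET from this personalized baseline.

Because the clinical and ADNI cohorts behind this methodology are
restricted, the package ships a phantom simulator that reproduces the
statistical structure the method depends on, so every stage — training
included — can be exercised and tested end to end on one CPU.

## The model

Two stacked Pix2Pix-style conditional GANs share one 3D U-Net generator
architecture and one 3D PatchGAN discriminator architecture:

* the **sketcher** generator maps an MRI patch to a draft PET patch;
* the **refiner** generator receives the MRI patch concatenated with the
  (gradient-detached) sketch and produces the final patch.

Each stage keeps its own discriminator, which sees (MRI, candidate-PET)
channel pairs and classifies overlapping sub-patches as real or synthetic.
The losses are:

* adversarial: ordinary binary cross-entropy on the discriminator's
  probability field (probabilities clamped by 1e-7 for numerical safety);
* recognition: L1 confined to the brain mask, so sentinel voxels outside
  the dilated mask can never influence optimization;
* for the refiner only, an additional gray-matter-masked L1 term
  (GM probability > 0.5) that emphasizes the tissue most relevant to
  neurodegenerative disease.

The default weights (`lossWeights()`) are adversarial 1, brain L1 100, GM
L1 100 — the Pix2Pix convention of letting the reconstruction term
dominate, which keeps the adversarial game stable at small batch sizes.

Volumes are processed as patches of 32 neighbouring full sagittal slices.
At inference all stride-1 patches are synthesized and fused with a
weighted average whose weight falls off linearly with the slice's distance
to its patch centre (`fusionWeightProfile()`). Stride-1 tiling of `S`
slices yields `S - w + 1` start positions, which guarantees coverage of
both edge slices; a `dropLast` option reproduces the alternative
edge convention with one position fewer. The triangular profile is the
simplest strictly decreasing choice; Gaussian and uniform profiles are
available, and fusing patches extracted from any volume reproduces that
volume exactly regardless of the profile (a partition-of-unity property
the tests assert at 1e-12).

### Scale presets

`archConfig("full")` follows the production-scale plan: U-Net channels
64–2048 over six resolution levels, for a trainable-parameter count near
2e8 across the four networks (reported by `countParameters()` from layer
shapes alone). `archConfig("desk")` is the preset actually trained in the
tests and the acceptance study: three levels with channels (2, 8, 16),
batch size 1, the same patch geometry at a 64-voxel grid. Its decoder
first reduces each skip concatenation with a 1x1x1 convolution before the
3x3x3 convolution, which keeps full-resolution arithmetic proportional to
the small channel count. The engine underneath is a purpose-built float32
conv-net core (im2col + BLAS GEMM with hand-written backprop and ADAM),
verified against a double-precision R reference implementation by
directional-derivative checks.

### Desk training schedule

The production schedule — ADAM, initial rate 1e-4, 10-fold decays at steps
20,000 and 50,000 of a 90,000-step pretraining run — is tied to its step
count and model size. A 2,000-step desk run at 1e-4 stops far short of
convergence (holdout error roughly three times worse in our calibration
runs), so `deskSchedule()` keeps ADAM and the two 10-fold decays but uses
an initial rate of 3e-3 with decays at 85% and 97% of the run. The
full-scale schedule remains the default of `trainSchedule()` and is what
`lrAtStep()` is tested against.

Training augmentations follow the stated distributions: sagittal mirroring
with probability 0.5, per-axis affine transformations (scale uniform in
(0.9, 1.1), rotation uniform in (-10, 10) degrees) with probability 1, and
a random multiplicative bias field on the MRI with probability 0.5. One
geometric transform is applied identically to images (trilinear) and masks
(nearest-neighbour). One desk-scale caveat matters here: the phantom's
cortical uptake crest is only one to two voxels wide, so trilinearly
resampling the *target* PET at every step measurably lowers that crest in
the training signal and biases the learned gray-matter uptake downward —
an artefact of the phantom's scale rather than of the recipe, since a
1 mm clinical cortex spans many more voxels. The desk study
(`runPipeline()` and the scaled-down training tests) therefore keeps the
mirroring and bias-field terms, which involve no interpolation, and
disables the affine term (`augmentConfig(pAffine = 0)`);
`augmentSample()` itself implements the full recipe and is tested against
it. Transfer learning is expressed as two stages:
`trainStage(..., sched = trainSchedule(stage = "pretrain"))` on the large
heterogeneous cohort, then `stage = "finetune"` initialized from the
pretrained bundle. A holdout split tracks a validation L1 and the returned
checkpoint is the best one seen (early stopping).

## Normalization

All operators act on already-registered, skull-stripped volumes (the
external tools that produce such volumes — bias correction,
skull-stripping, registration, segmentation — are out of scope; phantoms
are generated aligned and segmented).

* **Mask dilation** (`dilateMask`): exact Euclidean dilation by a
  millimetre radius (default 10 mm) via an exact distance transform,
  honouring anisotropic spacing.
* **MRI z-normalization** (`znormalizeMri`): mean and *population* SD
  computed only over voxels depicting gray or white matter
  (gm + wm > 0.5), which decouples the normalization from ventricular and
  sulcal CSF volume and hence from atrophy. Voxels outside the dilated
  mask are set to the sentinel -7 exactly, and the sentinel is excluded
  from every loss and metric.
* **PET normalization** (`normalizePet`): division by the mean of the
  top-2% gray/white-matter voxels of the 3-mm-blurred PET. "3 mm" is
  interpreted as FWHM (the PET reconstruction convention), so
  sigma = 3 / (2 sqrt(2 ln 2)) ≈ 1.27 mm. "Top 2%" means values at or
  above the 98th percentile (type-7 linear interpolation), ties included;
  both the selection and the average use the blurred intensities. The
  blur affects only the constant — the returned volume is the unblurred
  PET divided by it — and the constant is stored so `denormalize()` can
  recover original units.
* **Grid standardization** (`cropPadToCube`): centred crop/pad with the
  larger share of any uneven split going to the high-index side, and the
  voxel-to-world affine updated so retained voxels keep their world
  coordinates.

## Abnormality mapping

For a subject with true PET `Y` and synthetic baseline:

1. a healthy-uptake region is defined on the **true** PET — the
   gray/white-matter voxels with top-2% uptake after a 3 mm blur;
2. the sbPET is post-normalized by the ratio of region means, giving
   `Yhat` (this guards against global scale drift of the synthesis);
3. both volumes are blurred by 3 mm and the map
   `Z%(x) = 100 (Y(x) - Yhat(x)) / Yhat(x)` is evaluated inside the brain
   mask.

Negative Z% is hypometabolism, positive is hypermetabolism. Voxels where
the baseline is at or below 1e-6 times its mask mean are carried as
missing rather than clipped, and regional summaries
(`regionalSummary`) report empty regions as missing, never as zero.
`groupMeanMap` averages subject maps voxel-wise, counting only the maps in
which a voxel is defined. The ordering is post-normalize first, then blur,
then divide.

## The phantom simulator

`generatePhantom()` builds paired pseudo-MRI/pseudo-PET subjects from an
analytically controlled anatomy: concentric, randomly deformed ellipsoidal
shells — a CSF ventricle core, a WM shell, a cortical GM ribbon, a thin
outer CSF band — expressed through a smoothly perturbed normalized radius.
Key properties:

* tissue probabilities ramp linearly over a ~2-voxel shell at every
  interface, so partial-volume voxels exist and the top-2% and z-scoring
  rules are exercised non-trivially;
* PET uptake is the probability-weighted mix of per-tissue rates with
  GM:WM:CSF = 3:1:0.2 by default, the canonical FDG contrast;
* pseudo-T1w MRI uses WM > GM > CSF intensity means (0.85/0.55/0.20)
  with small within-tissue texture, a multiplicative low-frequency bias
  field (default peak 10%), and additive Gaussian noise;
* the default noise SD, 0.06, equals 2% of the GM uptake rate — chosen as
  a realistic post-reconstruction noise level for averaged static FDG
  frames and matching the noise condition of the lesion-recovery tests;
* atrophy is a scalar in [0, 1] that scales the ventricle outward and
  thins the GM ribbon, both linearly, making CSF/GM volume monotone in
  the scalar (a tested property);
* lesions are spheres in which uptake is multiplied by `1 - reduction`,
  optionally restricted to GM voxels, with the ground-truth mask recorded;
  the MRI is untouched, mimicking metabolic change without structural
  change;
* an octant atlas provides eight labelled regions for the region-wise
  readouts.

What the phantoms deliberately do **not** model: realistic MRI physics
(no k-space, no Rician noise), scanner-specific PET point-spread functions,
registration and segmentation errors, and the anatomical richness of real
cortex (gyri and sulci). Consequently, passing the phantom study shows the
pipeline's machinery is correct and that the model can learn an
anatomy-conditioned uptake mapping under noise, bias and morphological
variability — it does not certify clinical-grade synthesis accuracy on
real data, whose headline numbers require the restricted cohorts.

## Problem sizes used by tests and the acceptance study

The test suite trains the desk preset on 40 phantom subjects at a
64-voxel grid for 2,000 steps and evaluates 5 healthy plus 5 lesioned
(30–40% reduction) holdout subjects; the acceptance script runs the same
desk study as a two-stage pipeline (28-subject pretraining cohort,
1,400 steps; 12-subject fine-tuning cohort, 600 steps) with the same
holdout design. Unit and property tests use 8³–64³ volumes and
brute-force oracles (exhaustive distance search, per-voxel loops,
closed-form OLS) frozen independently of the implementation.

## Numerical choices and degenerate inputs

* Population (divide-by-N) SD in the z-normalization; deterministic and
  standard in image normalization.
* Constant-intensity tissue raises an error ("degenerate intensity
  distribution") rather than returning infinities.
* The Gaussian kernel is truncated at 4 sigma and renormalised over its
  in-bounds support, so constants are preserved exactly at edges.
* RD%/Abs% exclude voxels whose true uptake is at or below 1% of the
  mask-mean, preventing near-zero CSF denominators from dominating; the
  PSNR peak is the masked maximum of the true image, which makes all
  three metrics exactly invariant to joint rescaling.
* BCE probabilities are clamped to [1e-7, 1 - 1e-7].
* Fusion normalizes by the per-voxel weight sum, so volume edges (covered
  by fewer patches) are handled exactly.
* All randomness flows from explicit seeds; phantom regeneration under a
  changed atrophy keeps the same morphological noise because draw order
  is independent of the atrophy value.

## Known limitations

* The desk-scale model is intentionally tiny; its synthesis error on
  phantoms (Abs% in the tens of percent at low-uptake CSF voxels) is far
  from what the full-scale architecture achieves on clinical data.
* Training is single-threaded CPU float32; determinism holds for a fixed
  machine and BLAS, which is the reproducibility contract the tests
  assert.
* The simulator's atlas is a coordinate octant partition, sufficient for
  region-wise machinery but not anatomically meaningful.
* Nonlinear spatial normalization is out of scope: phantom cohorts share
  one grid, so group averaging is a plain voxel-wise mean.
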
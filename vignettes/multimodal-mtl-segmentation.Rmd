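---
title: "Multi-modality MTL subregion segmentation at desk scale: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modality MTL subregion segmentation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtlseg)
```

## What this package models

Hippocampal subfields (CA1-3, dentate gyrus, subiculum, the unpartitioned
posterior tail) and the adjacent parahippocampal cortices (ERC, BA35, BA36,
PHC) are small, thin, curved structures whose boundaries are only visible on
dedicated high-resolution T2-weighted MRI. In practice a study collects
several complementary scans per participant — here five channels in a fixed
order: 7T-T2w (the primary contrast in whose grid the segmentation is
produced), the two 7T MP2RAGE inversion contrasts (INV1, INV2), a dedicated
partial-coverage 3T-T2w scan, and a whole-brain 3T-T1w scan. The quality of
the primary 7T-T2w varies substantially across participants; a model that
silently over-relies on it fails exactly on the scans where automation is
most needed.

`mtlseg` implements, at desk scale and fully synthetically, the complete
chain this setting requires:

1. a **phantom generator** producing five-channel volumes with nested
   multi-label geometry, controllable quality, misalignment, longitudinal
   atrophy and cohort structure;
2. the **rigid registration cascade** that brings every channel into the
   primary frame (NMI and neighborhood-NCC metrics, a multiresolution
   coordinate-descent optimizer, the indirect path for the partial-coverage
   scan, ROI mapping and patch cropping, local refinement);
3. **ModAug**, the training-time channel-replacement augmentation;
4. a small 3D **encoder-decoder segmentation network** trained with a
   Dice + BCE deep-supervision loss under subject-level cross-validation
   with ensembled inference;
5. the **evaluation suite**: Dice overlap, tail-adjusted volumetry,
   anterior-posterior normalization, longitudinal ICC(2,1) and
   Bland-Altman agreement, covariate-adjusted group discrimination, and
   segmentation-quality rejection arithmetic.

Everything runs on a single CPU in minutes. Nothing requires real MRI.

## The phantom and what it does (and does not) emulate

The phantom is a parametric curved tube whose cross-section is partitioned
angularly into CA1/CA2/CA3/SUB with a dentate core, a posterior tail
segment, cortical ribbons below the tube split along the
anterior-posterior axis into ERC/BA35/BA36/PHC, and thin sulcal labels
(HS, CS) plus small Cysts/MISC structures. Each channel paints the label
map through a per-channel contrast table, then applies a smooth
multiplicative bias field and additive Gaussian noise (Rician optionally).
The 3T-T2w channel is exactly zero outside a central anterior-posterior
coverage window, emulating a dedicated partial-coverage acquisition; about
40% of the extent is uncovered.

The contrast table is designed so that the primary 7T-T2w separates every
label with the largest margins (it is the contrast the anatomical protocol
is defined on), while the secondary channels are individually weaker but
jointly informative — the property that makes multi-modality input
worthwhile in the first place. This is a deliberate caricature: real
tissue contrast is spatially heterogeneous, boundaries are fuzzy at the
resolution limit, and artifacts are structured (motion ghosting,
susceptibility), none of which the phantom reproduces. Passing tests on
phantoms therefore demonstrate that the *operators* are correct and that
the *training dynamics* behave as designed — they do not certify accuracy
on real MRI.

Key defaults (all in `phantom_config()`):

* grid 64^3 at 0.5 mm isotropic (training patches use 32^3 at 0.8 mm);
* tube radius 6 mm, dentate core at 0.45 of the radius, posterior 20%
  assigned to the tail, cortical ribbon 2.2 mm thick;
* per-channel noise SD 0.02 on a unit intensity scale, bias-field
  amplitude 0.05;
* `volume_scale` rescales gray-matter structures: the tube radius scales
  with its square root and ribbon thickness linearly, so rendered
  volumes track the factor up to voxelization error.

## Image quality model

Raters grade 7T-T2w quality on a 1-9 scale with 5 as the high-quality
threshold; three ratings are averaged and rounded. The mapping from a
rating to a concrete degradation is not quantified anywhere in terms of
image statistics, so it is a free calibration that we fix once:
severity `s = (9 - rating)/8` drives a Gaussian blur of `3s` mm, a
compression of inter-tissue contrast toward the image mean by a factor
`1 - 0.85 s`, and additive noise of SD `0.15 s`. The anchor is the
operational meaning of the scale's ends: at rating 9 the image is
untouched (bit-identical; the no-op is explicit in the code), and at
rating 1 internal subfield boundaries are essentially invisible, which is
what makes a scan "poor" to a rater. Degradation affects only channel 1;
the isolation is contractual and tested. Sharpness, measured as
gradient-magnitude energy, is monotone in the rating.

## Registration cascade

All channels are registered rigidly to the 7T-T2w frame:

* **INV1 to 7T-T2w** with normalized mutual information (NMI, 32 bins,
  intensities clipped at the 1st-99th percentiles); INV2 reuses INV1's
  matrix since both inversions come from one acquisition;
* **3T-T1w to 7T-T2w** with NMI;
* **3T-T2w** inherits the 3T-T1w matrix rather than being registered
  directly: its zero-valued uncovered region would otherwise enter the
  similarity metric and bias the fit. The simulator reproduces this
  hazard (the two 3T scans share motion up to a small residual).

The optimizer is a gradient-free coordinate descent over the six rigid
parameters (Euler angles and translation about the fixed-image center,
matching a center-alignment initialization), run on an image pyramid with
100/50/10 iterations at 4x/2x/1x. Steps start at one coarse voxel and
2 degrees and halve when no axis improves; the returned transform never
scores below its initialization. NMI bin count, optimizer type and
convergence tolerances are declared choices — the reference registration
tool does not document its internals.

After whole-image registration, an MTL region of interest is mapped from a
template: we substitute an affine (rigid) fit plus a safety margin for the
deformable template registration, because only the ROI bounding box is
consumed downstream and the margin (default 4 mm, 2 mm in the pipeline's
phantom setting where geometry is shared) absorbs the residual. Local
refinement then re-estimates each secondary channel within the patch,
using neighborhood NCC (5x5x5 windows) for INV1, NMI for 3T-T1w, and
weighted NCC for 3T-T2w with the coverage mask as weights. The moving
image of the local step is the full channel, not the cropped patch: a
cropped moving image loses context at the patch border and its zero fill
can pull the metric optimum away from the truth (we observed exactly this
failure with patch-to-patch refinement). On phantoms, refinement from an
imperfect initialization improves the ground-truth residual; from an
already sub-voxel initialization it may wander within about a quarter
voxel, because the patch-metric optimum and the global truth differ at
that scale — the corresponding test asserts improvement from coarse
initializations and a quarter-voxel bound from accurate ones.

## ModAug

During training each iteration enters an augmentation branch with
probability 0.5; inside the branch, k is drawn from {1,2,3,4} with equal
probability and k channels (never all five) are replaced by filler
content. The default filler is i.i.d. standard normal noise on the
z-normalized intensity scale; all-zero channels and donor channels from
another participant are available as variants. Whether the original
implementation protected the primary channel from replacement, or
replaced INV1/INV2 jointly, is not documented; both are configuration
switches here, defaulting to per-channel replacement with the primary
eligible. ModAug is strictly a training-time device: inference always
sees the full stack.

## Network, loss and training

The backbone is deliberately not the contribution, so it is a fixed plain
3D U-Net: two 3x3x3 convolutions per encoder level (leaky rectifier,
slope 0.01), average-pool downsampling, nearest-neighbor upsampling with
skip concatenation, 1x1x1 class heads, and one auxiliary deep-supervision
head at the coarser level with level weights halving per level and
normalized to sum one. Desk-scale defaults are depth 2 and base width 8
(width 6 in the robustness experiment) on 32^3 patches — a few thousand
parameters, approximately forty thousand weights, trained by Adam at
learning rate 0.02 with global-norm gradient clipping at 5 and two
step-downs late in training. The leaky rectifier matters: with hard
rectifiers this narrow network collapses into dead units at useful
learning rates. Forward, backward and the optimizer are implemented in
the package, with the convolution and loss kernels in compiled code;
gradients are verified against finite differences in the test suite.

The loss is the sum of a soft-Dice term (class-mean, smoothing 1e-5) and
one-vs-rest binary cross-entropy per class (probabilities clipped at
1e-7), evaluated at each supervision level on block-averaged targets.
"BCE" follows the protocol's naming; categorical cross-entropy is not
used. The full-scale regime this mirrors trains 400 epochs; desk-scale
defaults train 20-100 depending on the experiment, with the problem sizes
chosen so each experiment completes in minutes on one CPU.

Cross-validation splits subjects, not patches: both sides of a subject
share a fold. Right-side patches are mirrored to the left before entering
the network and predictions are mirrored back; ensembling averages
per-class probabilities across fold models before the argmax.

## Evaluation suite

* **Dice**: `2|A∩B|/(|A|+|B|)`, defined as 1 for two empty masks.
* **Tail adjustment**: subfield volumes are multiplied by
  `(subfields + tail)/subfields`, so the adjusted subfields sum exactly
  to the total hippocampal volume and the unpartitioned tail drops out of
  downstream analysis.
* **A-P normalization**: cortical volumes are divided by the physical
  anterior-posterior extent of their label support,
  `(max slice − min slice + 1) × slice spacing`.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the ANOVA mean squares. The protocol names only
  "intraclass correlation"; ICC(2,1) is the standard test-retest choice
  and is fixed here.
* **Bland-Altman**: differences t2−t1, limits at the mean ± 1.96 sample
  SDs (n−1 denominator).
* **Group discrimination**: a linear model `value ~ group + age + ICV`
  for volumes (`+ age` only for thickness, which is consumed from an
  input column, never computed here); p is the two-sided test of the
  group coefficient. AUC and Cohen's d are computed on
  covariate-residualized values (the residualization is a declared
  choice — the source tables do not state one), oriented
  control-minus-patient and never flipped, so AUC below 0.5 is a valid
  outcome.
* **Rejection arithmetic**: from a 3x3 good/uncertain/bad confusion
  matrix, strict rejection counts uncertain+bad, lenient counts bad only;
  reductions are relative drops from the single-modality to the
  multi-modality column margins. Both variants are first-class because
  both appear in the published arithmetic. Percentages round half away
  from zero at 2 decimals to match printed values.

## The robustness experiment

The headline property is directional, not a Dice value: full-scale Dice
tables require real paired 3T/7T MRI and GPU-scale training. The
experiment trains two identically seeded networks per replicate — with
and without ModAug — on subjects with clean primaries, then compares mean
foreground Dice on test subjects whose primaries are degraded to ratings
1-3. Two conditions proved necessary for the effect to appear, both
consistent with the mechanism it mirrors: the networks must be trained
near convergence (an undertrained pair shows only noise; with ModAug
consuming half the clean iterations its twin converges later), and
training must include the standard intensity jitter, which pushes the
plain network away from per-voxel intensity lookups toward the spatial
detail of the sharpest channel — the over-reliance that degrades when
that channel blurs. The acceptance configuration is 5 seed replicates,
4 training subjects, 75 epochs, width 6, 32^3 patches.

## Numerical and degenerate-input choices

* NMI errors on (near-)constant images; local NCC windows with zero
  variance contribute 0; the weighted variant averages per-center weights.
* Resampling fills out-of-field voxels with 0; label maps must use
  nearest-neighbor interpolation (linear interpolation of codes is a
  contract error).
* Argmax ties in ensembling resolve to the lowest class index.
* Means of three integer ratings are never exactly .5, so the final
  rating is well defined under round-half-away-from-zero.
* Empty labels yield zero volumes with a warning; zero A-P extent and
  zero subfield sums are errors.
* All generators are pure functions of (config, seed); the RNG state of
  the caller is saved and restored.

## Known limitations

* The phantom's geometry is smooth and its noise unstructured; no claim
  about real-MRI accuracy follows from phantom Dice.
* The affine ROI substitute assumes template and subject differ by a
  rigid motion plus a margin; real anatomy needs the deformable fit it
  replaces.
* The quality scale's physical calibration is a package choice; only its
  monotonicity and endpoints are anchored.
* The network is far below the capacity and training budget of a
  production segmentation model; it exists to carry the training-scheme
  comparison, not to segment well in absolute terms.
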
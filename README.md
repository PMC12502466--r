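# mtlseg

Desk-scale, fully synthetic implementation of a multi-modality MRI pipeline
for medial temporal lobe (MTL) subregion segmentation, aimed at method
developers and reviewers who want every stage of such a pipeline —
registration, augmentation, training, evaluation — runnable and testable on
one CPU without any real MRI.

## The problem

Hippocampal subfields (CA1–CA3, dentate gyrus DG, subiculum SUB, the
unpartitioned posterior Tail) and parahippocampal cortices (ERC, BA35,
BA36, PHC) are segmented on a high-resolution 7T-T2w scan, with four
complementary channels stacked alongside it in a fixed order: 7T-T2w,
7T-T1w INV1, 7T-T1w INV2, 3T-T2w (dedicated, partial coverage), 3T-T1w.
The quality of the primary 7T-T2w varies widely, and a network trained on
high-quality scans tends to over-rely on it — failing exactly on the scans
where automation matters most. The pipeline's remedy is **ModAug**:
during training, with probability 1/2 an input enters an augmentation
branch where k ∈ {1,2,3,4} of the five channels (equal probability, never
all five) are replaced by noise, forcing the network to exploit every
modality.

The package implements:

* a parametric **phantom generator** (curved-tube hippocampus plus
  cortical ribbons, 15-label protocol, per-channel contrast, bias field,
  noise, quality degradation, misalignment, longitudinal atrophy in the
  reported 0.2–2.55 %/yr range, two-group cohorts);
* the **rigid registration cascade** to the 7T-T2w frame: NMI
  (`(H(a)+H(b))/H(a,b)`) and 5×5×5 neighborhood-NCC metrics, weighted NCC
  for the partial-coverage scan, a multiresolution (100/50/10 at 4×/2×/1×)
  coordinate-descent optimizer, the indirect 3T-T2w path through the
  3T-T1w matrix, template-ROI mapping, patch cropping, local refinement;
* **ModAug** and the right-to-left flip normalization;
* a small 3D U-Net with Dice+BCE deep-supervision loss, five-fold
  subject-level cross-validation and ensembled inference (forward,
  backward and Adam implemented in the package, conv kernels in C++);
* the **evaluation suite**: Dice, tail-adjusted volumetry
  (`R = (Σ subfields + Tail)/Σ subfields`), anterior–posterior length
  normalization, ICC(2,1), Bland–Altman limits (±1.96 SD),
  covariate-adjusted group discrimination (p, AUC, Cohen's d on
  age/ICV-residualized values), and segmentation-quality rejection
  statistics with strict (uncertain+bad) and lenient (bad-only) rules.

## Worked example

Rejection arithmetic from a qualitative confusion matrix (single-modality
model on rows, multi-modality on columns):

```r
library(mtlseg)
cm <- qual_confusion(rbind(c(227, 11, 0),
                           c(42, 28, 0),
                           c(31, 4, 1)))
str(rejection_stats(cm))
#> List of 8
#>  $ total                : num 344
#>  $ strict_single_pct    : num 30.8
#>  $ strict_multi_pct     : num 12.8
#>  $ lenient_single_pct   : num 10.5
#>  $ lenient_multi_pct    : num 0.29
#>  $ strict_reduction_pct : num 58.5
#>  $ lenient_reduction_pct: num 97.2
#>  $ undefined            : logi FALSE
```

30.81 % of single-modality segmentations are rejected under the strict
rule versus 12.79 % for the multi-modality model — a 58.49 % reduction
(97.22 % under the lenient rule).

Phantoms, volumetry and the tail adjustment:

```r
ph <- generate_phantom(phantom_config(seed = 42))
ph$stack
#> modality_stack: 64x64x64 voxels, spacing 0.5x0.5x0.5 mm, 5 channels
v <- subregion_volumes(ph$labels)          # mm^3 per region
vols <- setNames(v$value, v$region)
round(tail_adjust(vols), 1)
#>   CA1   CA2   CA3    DG   SUB
#> 600.6 302.9 361.9 525.2 904.7
sum(tail_adjust(vols)) == sum(vols[c("CA1","CA2","CA3","DG","SUB","Tail")])
#> [1] TRUE
```

The adjusted subfields absorb the unpartitioned tail exactly.

Longitudinal consistency on simulated scan pairs (1.5-year interval,
1.5 %/yr atrophy, per-subject size variation):

```r
set.seed(9)
scales <- exp(rnorm(8, 0, 0.08))
pairs <- t(sapply(1:8, function(i) {
  cfg <- phantom_config(grid_shape = c(48, 48, 48),
                        spacing_mm = rep(0.6, 3), seed = i,
                        region_geometry = list(volume_scale = scales[i]))
  p <- generate_longitudinal_pair(cfg,
         cohort_spec(atrophy_rate_per_year = 0.015, seed = 1), 1.5)
  hip <- c("CA1","CA2","CA3","DG","SUB","Tail")
  c(sum(p$volumes$v1[p$volumes$region %in% hip]),
    sum(p$volumes$v2[p$volumes$region %in% hip]))
}))
icc_consistency(pairs)$icc
#> [1] 0.933
unlist(bland_altman(pairs))
#> mean_diff -55.4 mm^3, limits [-61.5, -49.3]
mean(pairs[, 2] / pairs[, 1])   # 0.9768; (1 - 0.015)^1.5 = 0.9776
```

The measured volume ratio matches the configured atrophy to voxelization
accuracy, and the ICC reflects stable between-subject ordering across
timepoints.

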
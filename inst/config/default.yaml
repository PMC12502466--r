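# Default desk-scale pipeline configuration.
# Protocol constants carried here:
#   - channel order: 7T-T2w, 7T-T1w INV1, 7T-T1w INV2, 3T-T2w, 3T-T1w
#   - ModAug: 50% augmentation branch, equal weights over k = 1..4
#   - registration schedule: 100/50/10 iterations at 4x/2x/1x resolution
#   - quality threshold: rating >= 5 is high quality
#   - agreement limits: mean difference +/- 1.96 SD
n_train: 4
n_test: 2
seed: 1
patch_size: 32
epochs: 10
n_folds: 2
base_width: 8
grid_shape: [48, 48, 48]
spacing_mm: [0.7, 0.7, 0.7]
test_quality_range: [2, 8]
modaug: true
misalign_mm: 2.0
misalign_deg: 3.0
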
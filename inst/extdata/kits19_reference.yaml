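# Reference pipeline configuration: multi-class kidney/tumor segmentation
# of abdominal CT volumes (background / kidney / tumor).  Documents the
# full-scale setup; the values are far beyond desk scale and are shipped
# as documentation of a complete configuration, not as a test fixture.
data:
  interface: nifti
  root: data/kits19
preprocessing:
  clip_lo: -79            # Hounsfield window for kidney CT
  clip_hi: 304
  normalization: zscore
  target_spacing: [3.22, 1.62, 1.62]   # mm per voxel
  n_classes: 3
patches:
  patch_shape: [80, 160, 160]
  overlap: [40, 80, 80]   # applied when building the prediction grid
  analysis: patchwise-crop  # training patches via random cropping
  skip_blanks: true
  crops_per_sample: 1
augmentation:             # all implemented operators enabled
  p_mirror: 0.15
  p_rotate: 0.15
  p_scale: 0.15
  p_elastic: 0.15
  p_brightness: 0.15
  p_contrast: 0.15
  p_gamma: 0.15
  p_noise: 0.15
model:
  architecture: unet
  n_dims: 3
  n_classes: 3
  base_filters: 32
  depth: 4
  batch_norm: true
  dropout: 0.0
training:
  batch_size: 2
  epochs: 1000
  learning_rate: 1.0e-4
  loss: tversky
  monitor_metrics: [dice_soft, dice_classwise, crossentropy_dice]
evaluation:
  mode: kfold
  k: 3
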
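# Demo pipeline configuration: a small synthetic condition series
# (healthy / OGD / BEV at 24 h and 48 h) run end to end.
mode: synthetic
out_dir: micromorph_demo
seed: 1
synthetic:
  image_shape: [300, 300]
  n_cells: 8
  noise_sd: 0.02
  n_images: 1
segmentation:
  method: li
  min_object_area_px: 71
  pixel_size_um: 1.0
shape_modes:
  k: 3
  n_points: 50
  train_fraction: 0.8
stats:
  alpha: 0.05
  adjustment: bonferroni
  statistic: median
  control: healthy
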
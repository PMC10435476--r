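seed: 1.0
outdir: pamgan-demo
phantom:
  kind: vessels
  extent_um:
  - 640.0
  - 250.0
  - 1280.0
  n_seeds: 6
  branch_prob: 0.15
  diameter_range_um:
  - 18.0
  - 30.0
  tortuosity: 0.3
pitches:
  dx: 10.0
  dy: 10.0
  dz: 20.0
psf:
  ar:
    lateral_fwhm_focus_um: 80.0
    axial_fwhm_um: 27.0
    focal_depth_um: 640.0
    depth_of_focus_um: 1500.0
    out_of_focus_growth: 0.002
    attenuation_length_um: 1500.0
    max_visible_depth_um: 1900.0
  or:
    lateral_fwhm_focus_um: 12.0
    axial_fwhm_um: 27.0
    focal_depth_um: 640.0
    depth_of_focus_um: 1000.0
    out_of_focus_growth: 0.01
    attenuation_length_um: 1500.0
    max_visible_depth_um: 1000.0
noise:
  ar:
    gaussian_sigma: 0.02
    salt_pepper_density: 0.0
  or:
    gaussian_sigma: 0.005
    salt_pepper_density: 0.005
simulate:
  n_volumes: 8
preprocess:
  patch_size: 64
  stride: 64
model:
  n_res_blocks: 2
  base_filters: 8
  n_downsamples: 2
train:
  mode: cgan
  epochs: 15
  lr: 0.0002
  lr_decay_factor: 0.5
  lr_decay_epochs: []
  l1_weight: 100.0
  cycle_weight: 25.0
  adv_loss: lsgan
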
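# Demo pipeline run: synthetic femoral head, three cysts, full panel.
seed: 1
output_dir: cysthead_demo
phantom:
  head_radius: 10
  voxel_size: 0.25
  bone_fraction_target: 0.45
  strut_scale: 0.14
  rim_thickness: 0.3
  anisotropy_stretch: 1.3
  cortical_thickness: 0.6
  noise_sd: 8
  blur_sigma: 0.05
  cysts:
    - centre: [3, 2, 2]
      diameter: 3
    - centre: [-4, -1, 1]
      diameter: 2
    - centre: [0, -3, -3.5]
      diameter: 1.5
detect:
  lo: 90
  hi: 255
  min_diameter: 1.0
  step: 0.5
  connectivity: 26
  restore: opening
  closing_radius: 1.5
segment:
  fractions: [0.30, 0.40, 0.30]
morpho:
  enabled: true
  shell_width: 0.5
  n_directions: 128
write_volumes: false
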
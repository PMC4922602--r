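# Example study configuration: a small cohort with shared-gloss and
# 3D-structure voxel populations in every ROI.
seed: 1
n_subjects: 12
run_range:
  binocular: [7, 10]
  nonstereoscopic: [8, 10]
rois: [V3B, LO, pFs]
model:
  n_voxels: 60
  fractions: {shared: 0.1, structure: 0.15}
  amplitude: 1.5
  noise_sd: 1.0
  hrf_lag: 4
n_perm: 1000
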
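# Scenario 2: variable-density stack of spirals at 3 mm resolution,
# 14 shots per volume (TR_vol = 0.7 s), 8 coils, T2* engine,
# SURE-tuned CS reconstruction (refined strategy).
phantom:
  shape: [64, 64, 60]
  voxel_size: 3
  seed: 1
roi:
  center: [0.0, -65.0, 0.0]
  semiaxes: [25.0, 25.0, 25.0]
  gm_threshold: 0.5
paradigm:
  on_s: 20
  off_s: 20
bold:
  delta_R2s: -1
sequence:
  TR_shot: 50
  TE: 25
  FA: 12
  Tobs: 30
trajectory:
  kind: sos
  n_samples: 3000
  n_turns: 12
  n_center: 6
  n_outer_per_frame: 8
  dynamic: true
engine:
  kind: t2s
  snr_in: 1000
  L: 8
recon:
  method: cs
  strategy: refined
  mu: auto
  wavelet:
    family: sym8
    levels: 2
  solver:
    algorithm: pogm
    max_iter: 50
    tol: 1.0e-5
analysis:
  p: 0.001
run:
  length_s: 300
  seed: 1
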
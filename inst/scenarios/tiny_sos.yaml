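# Desk-scale accelerated run: 16^3 matrix, dynamic variable-density
# stack of spirals, 2 coils, T2* engine, SURE-tuned CS reconstruction
# with the refined initialization strategy.
phantom:
  shape: [16, 16, 16]
  voxel_size: 3
  seed: 1
roi:
  center: [0.0, -15.0, 0.0]
  semiaxes: [9.0, 9.0, 9.0]
  gm_threshold: 0.5
paradigm:
  on_s: 10
  off_s: 10
bold:
  delta_R2s: -1
sequence:
  TR_shot: 50
  TE: 25
  FA: 12
  Tobs: 30
trajectory:
  kind: sos
  n_samples: 256
  n_turns: 8
  center_frac: 0.15
  AF: 3
  dynamic: true
engine:
  kind: t2s
  snr_in: 1000
  L: 2
recon:
  method: cs
  strategy: refined
  mu: auto
  wavelet:
    family: sym8
    levels: 2
  solver:
    algorithm: pogm
    max_iter: 15
    tol: 1.0e-4
analysis:
  p: 0.001
run:
  length_s: 30
  seed: 1
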
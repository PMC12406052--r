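# Scenario 3: externally optimized full-3D readout imported from a
# trajectory file (set trajectory.path before running), 32 coils,
# reduced input SNR, cold-start CS reconstruction.
phantom:
  shape: [64, 64, 64]
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
  Tobs: 25
trajectory:
  kind: import
  path: sparkling.traj
engine:
  kind: t2s
  snr_in: 30
  L: 32
recon:
  method: cs
  strategy: cold
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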
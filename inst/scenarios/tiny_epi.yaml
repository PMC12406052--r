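# Desk-scale fully sampled Cartesian run: 16^3 matrix, 3D EPI,
# single coil, adjoint (inverse FFT) reconstruction.
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
  Tobs: 25
trajectory:
  kind: epi
engine:
  kind: basic
  snr_in: 1000
  L: 1
recon:
  method: adjoint
analysis:
  p: 0.001
run:
  length_s: 40
  seed: 1
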
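# Scenario 1: fully sampled 3D EPI at 3 mm isotropic resolution,
# single coil, 5-minute run, adjoint reconstruction.
phantom:
  shape: [60, 71, 60]
  voxel_size: 3
  seed: 1
roi:
  center: [0.0, -70.0, 0.0]
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
  kind: epi
engine:
  kind: t2s
  snr_in: 1000
  L: 1
recon:
  method: adjoint
analysis:
  p: 0.001
run:
  length_s: 300
  seed: 1
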
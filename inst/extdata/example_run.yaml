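# Example run configuration for the smlmgan CLI.
# `smlmgan simulate --config example_run.yaml --out outdir` generates a
# degraded stack plus ground truth; the same file drives localization and
# training subcommands.
acquisition:
  fov: 64              # camera pixels (square)
  pixel_size: 100      # nm per camera pixel
  psf_sigma: 130       # nm
  density: 6           # emitters per um^2 per frame
  n_frames: 200
  photons_per_emitter: 1000
  photon_mode: fixed
  upsample: 5
  sensor: huawei_p9
  compression:
    quality: 90
detection:
  filter_sigma: 1.3
  peak_threshold_k: 3
loss:
  lambda_cgan: 3
  lambda_l1: 100
  lambda_l1s: 100
training:
  learning_rate: 1.0e-4
  adam_beta1: 0.25
  batch_size: 4
  epochs: 10
seed: 1
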
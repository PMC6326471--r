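# Sensor presets for smlmgan::sensor_preset().
#
# huawei_p9: the values tied to the mean-variance calibration
#   procedure of the Huawei P9 monochrome chip at ISO 3200 (gain constant
#   up to ~220 ADU).
# huawei_p9_alt_rn: same sensor, but with an alternative reported
#   read-noise figure of 1.23 e- RMS.
# emccd_ixon: Andor iXon emCCD reference camera. Only bit depth, read
#   noise and QE are reported for this camera; gain and offset here
#   are SYNTHETIC typical values for an EM-amplified sensor (effective
#   gain << 1 e-/ADU, baseline clamp ~100 ADU) supplied so the preset is
#   usable in simulations.
huawei_p9:
  gain: 0.69
  offset: 4.1
  read_noise: 2.5
  bit_depth: 12
  linear_max: 220
  qe: 0.75
huawei_p9_alt_rn:
  gain: 0.69
  offset: 4.1
  read_noise: 1.23
  bit_depth: 12
  linear_max: 220
  qe: 0.75
emccd_ixon:
  gain: 0.02
  offset: 100
  read_noise: 0.2
  bit_depth: 14
  linear_max: 16383
  qe: 0.9
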
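# Example run configuration for the mcdem CLI (coarse MCC grade).
# Units: SI unless noted; PSD quantiles in micrometres.
material:
  young_modulus: 2.58e8
  poisson_ratio: 0.30
  density: 1541.1
  restitution_pp: 0.352
  restitution_pw: 0.352
  sliding_friction_pp: 0.561
  sliding_friction_pw: 0.707
  rolling_friction_pp: 0.3
  rolling_friction_pw: 0.01
  wall_young: 7.62e10
  wall_poisson: 0.31
psd:
  x10: 82.9
  x50: 224.6
  x90: 379.3
contact:
  k2_over_k1: 120
  kc_over_k1: 0.5
  phi_f: 0.99
  beta: 1.3
packing:
  box_mm: 0.5
  target_fraction: 0.59
  seed: 1
loading:
  max_strain: 0.5
  decompress: false
control:
  n_steps: 1.0e5
probe:
  radius_um: 112.3
  waypoints_um: [30, 5, 25, 0]
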
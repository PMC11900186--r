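# Example run configuration: osmotic volume sweep of a three-way junction
# at the biomimetic scale (all quantities in relaxation-length units).
geometry:
  kind: junction
  L0: 5.3            # arm length, per arm
  edge_target: 0.33  # mesh edge length
material:
  kappa: 1
  gamma0: 1
ensemble:
  length_mode: fixed_length
  area_mode: fixed_area
  volume_mode: fixed_volume
sweep:
  mode: volume
  from: 0
  to: 0.3
  steps: 12
solver:
  seed: 1
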
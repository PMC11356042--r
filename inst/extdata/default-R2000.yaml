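# Reference configuration: R2000 coil at the optimized operating point.
# Every key omitted here falls back to the same defaults, so this file is
# equivalent to `default_device_config("R2000")`.
coil:
  name: R2000
  current_mA: 400
channel:
  width_um: 50
  height_um: 50
  coil_separation_um: 30
fluid:
  flow_rate_uL_min: 1
  rel_permittivity: 80
particle:
  diameter_nm: 50
  rel_permeability: 5000
  rel_permittivity: 10
stack:
  wall_thickness_um: 5
  eps_wall: 2.7
simulation:
  horizon_s: 60
  n_particles: 500
  seed: 1
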
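name: epilc-1plex
description: Single-well EpiLC induction on a standard 24-well plate.
plate_type: standard-24
n_wells: 1
set_volume_uL: 750
dead_volume_uL: 0
fill_overshoot_fraction: 1.0
inflow_pressure_psi: 5
timing_s:
  empty: 45
  fill: 75
  level: 30
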
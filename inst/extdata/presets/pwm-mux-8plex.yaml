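name: pwm-mux-8plex
description: >
  Eight-well complex concentration patterns and EpiLC induction/reversion on
  imaging-compatible 24-well plates, served through the PWM-MUX path.
  Programmed phase times varied per well within the recorded ranges; the
  scalar values are the upper bounds (worst case per well).
plate_type: imaging-24
n_wells: 8
set_volume_uL: 750
dead_volume_uL: 0
fill_overshoot_fraction: 1.0
inflow_pressure_psi: 10
timing_s:
  empty: 120
  empty_range: [45, 120]
  fill: 180
  fill_range: [150, 180]
  level: 60
  level_range: [40, 60]
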
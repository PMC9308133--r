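name: gri3d-8plex
description: >
  Eight-well 3D gastruloid stimulation in Gri3D 3000 hydrogel microwell
  array plates (PWM-MUX). Full emptying retains 150 uL within the microwell
  arrays, protecting the aggregates; the fill time is the upper bound of the
  programmed range.
plate_type: gri3d-24
n_wells: 8
set_volume_uL: 1330
dead_volume_uL: 150
fill_overshoot_fraction: 1.0
inflow_pressure_psi: 10
timing_s:
  empty: 90
  fill: 270
  fill_range: [240, 270]
  level: 60
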
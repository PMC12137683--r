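# Example run configuration for rockersim.
# All keys are optional; anything omitted falls back to the defaults of the
# reference device (8 cm x 26 mm wells, water at 37 degC, 400-cell solver).
geometry:
  length_m: 0.08
  width_m: 0.026
  capacity_m3: 24.0e-6
motion:
  max_angle_deg: 7
  max_speed_deg_s: 40
fluid:
  temperature_C: 37
solver:
  n_cells: 400
  cfl_number: 0.4
  spinup_periods: 5
  record_periods: 1
analysis:
  fill_volume_mL: 5
  speeds_deg_s: [10, 20, 30, 40, 50, 70, 100]
  exceedance_threshold_Pa: 1
thermal:
  setpoint_C: 37
  duration_s: 1800
  kp: 0.3
  ki: 0.004
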
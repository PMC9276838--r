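kind: phantom
beaker_radius_mm: 65.0
beaker_height_mm: 145.0
pad_radius_mm: 50.0
electrode:
  nominal_diameter_mm: 40.0
  n_tines: 10
  deployed_fraction: 1.0
  tip_height_mm: 85.0
vessel:
  offset_mm: 25.0
  diameter_mm: 5.0
  flow_speed_mm_s: 105.0
  temperature_C: 20.0
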
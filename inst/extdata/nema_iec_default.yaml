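body:
  semi_axes_mm:
  - 150.0
  - 98.0
  length_mm: 208.9585307
spheres:
- diameter: 10.0
  x: 57.0
  'y': 0.0
  z: 0.0
  fill_volume: 0.5
  concentration: 35.4
- diameter: 13.0
  x: 28.5
  'y': 49.363448
  z: 0.0
  fill_volume: 1.0
  concentration: 35.4
- diameter: 17.0
  x: -28.5
  'y': 49.363448
  z: 0.0
  fill_volume: 2.8
  concentration: 35.4
- diameter: 22.0
  x: -57.0
  'y': 6.9804868e-15
  z: 0.0
  fill_volume: 5.8
  concentration: 35.4
- diameter: 28.0
  x: -28.5
  'y': -49.363448
  z: 0.0
  fill_volume: 11.7
  concentration: 35.4
- diameter: 37.0
  x: 28.5
  'y': -49.363448
  z: 0.0
  fill_volume: 29.0
  concentration: 35.4
lung_insert:
  diameter: 50.0
  length: 208.9585307
  concentration: 0.0
background_concentration_kbq_cm3: 11.0
total_fill_volume_cm3: 9650.0
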
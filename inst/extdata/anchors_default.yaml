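anchors:
- id: A1
  x: 0.0
  'y': 0.0
  z: 2.5
- id: A2
  x: 10.0
  'y': 0.0
  z: 2.5
- id: A3
  x: 10.0
  'y': 10.0
  z: 2.5
- id: A4
  x: 0.0
  'y': 10.0
  z: 2.5
- id: A5
  x: 5.0
  'y': 5.0
  z: 3.5
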
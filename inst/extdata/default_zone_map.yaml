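zones:
- vertex: 0
  name: snap_1
  role: snap_to_plate
  rect:
  - 0.0
  - 0.35
  - 0.25
  - 0.75
- vertex: 1
  name: snap_2
  role: snap_to_plate
  rect:
  - 0.25
  - 0.35
  - 0.5
  - 0.75
- vertex: 2
  name: snap_3
  role: snap_to_plate
  rect:
  - 0.5
  - 0.35
  - 0.75
  - 0.75
- vertex: 3
  name: snap_4
  role: snap_to_plate
  rect:
  - 0.75
  - 0.35
  - 1.0
  - 0.75
- vertex: 4
  name: plate_1
  role: plate
  rect:
  - 0.055
  - 0.38
  - 0.195
  - 0.71
- vertex: 5
  name: plate_2
  role: plate
  rect:
  - 0.305
  - 0.38
  - 0.445
  - 0.71
- vertex: 6
  name: plate_3
  role: plate
  rect:
  - 0.555
  - 0.38
  - 0.695
  - 0.71
- vertex: 7
  name: plate_4
  role: plate
  rect:
  - 0.805
  - 0.38
  - 0.945
  - 0.71
- vertex: 8
  name: food
  role: food
  rect:
  - 0.15
  - 0.78
  - 0.85
  - 1.0
- vertex: 9
  name: other_0
  role: other
  rect:
  - 0.0
  - 0.0
  - 0.25
  - 0.35
- vertex: 10
  name: other_1
  role: other
  rect:
  - 0.25
  - 0.0
  - 0.5
  - 0.35
- vertex: 11
  name: other_2
  role: other
  rect:
  - 0.5
  - 0.0
  - 0.75
  - 0.35
- vertex: 12
  name: other_3
  role: other
  rect:
  - 0.75
  - 0.0
  - 1.0
  - 0.35
- vertex: 13
  name: other_4
  role: other
  rect:
  - 0.0
  - 0.78
  - 0.15
  - 1.0
- vertex: 14
  name: other_5
  role: other
  rect:
  - 0.85
  - 0.78
  - 1.0
  - 1.0
- vertex: 15
  name: other_6
  role: other
  rect:
  - 0.0
  - 0.75
  - 1.0
  - 0.78
plate_parent:
  '4': 0
  '5': 1
  '6': 2
  '7': 3
screen_size:
- 1024.0
- 768.0
background: 15
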
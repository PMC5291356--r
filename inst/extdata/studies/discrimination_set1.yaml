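study_id: discrimination_set1
experiments:
- id: gratings
  cs: grating_horizontal
  cor: grating_horizontal
  inc: grating_vertical
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: 67.0
- id: sectors
  cs: sectors4
  cor: sectors4
  inc: sectors4_rot45
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: .na
- id: crosses
  cs: cross_plus
  cor: cross_plus
  inc: cross_diag
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: .na
- id: reversal_a
  cs: bars_axial_a
  cor: bars_axial_a
  inc: bars_axial_a_rev
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: 62.0
- id: spirals
  cs: spiral_cw
  cor: spiral_cw
  inc: spiral_ccw
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: 53.7
- id: reversal_b
  cs: bars_axial_b
  cor: bars_axial_b
  inc: bars_axial_b_rev
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: 65.0
- id: octagons
  cs: octagon_ring
  cor: octagon_ring
  inc: octagon_ring_rot
  offsets:
  - -200
  - -175
  - -150
  - -125
  - -100
  - -75
  - -50
  - -25
  - 0
  - 25
  - 50
  - 75
  - 100
  - 125
  - 150
  - 175
  - 200
  bee_pct: 56.4
recipes:
  grating_horizontal:
    family: bar_set
    uid: grating_horizontal
    params:
      bars:
      - angle: 0.0
        length: 140.0
        width: 20.0
        cx: 0.0
        cy: -50.0
      - angle: 0.0
        length: 140.0
        width: 20.0
        cx: -0.0
        cy: 0.0
      - angle: 0.0
        length: 140.0
        width: 20.0
        cx: -0.0
        cy: 50.0
  grating_vertical:
    family: bar_set
    uid: grating_vertical
    params:
      bars:
      - angle: 90.0
        length: 140.0
        width: 20.0
        cx: 50.0
        cy: -0.0
      - angle: 90.0
        length: 140.0
        width: 20.0
        cx: -0.0
        cy: 0.0
      - angle: 90.0
        length: 140.0
        width: 20.0
        cx: -50.0
        cy: 0.0
  sectors4:
    family: sector_disc
    uid: sectors4
    params:
      n_sectors: 4.0
      rotation: 0.0
  sectors4_rot45:
    family: sector_disc
    uid: sectors4_rot45
    params:
      n_sectors: 4.0
      rotation: 45.0
  cross_plus:
    family: cross
    uid: cross_plus
    params:
      rotation: 0.0
  cross_diag:
    family: cross
    uid: cross_diag
    params:
      rotation: 45.0
  bars_axial_a:
    family: quadrant_bars
    uid: bars_axial_a
    params:
      orientations:
      - 0.0
      - 90.0
      - 90.0
      - 0.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
  bars_axial_a_rev:
    family: mirror
    uid: bars_axial_a_rev
    params:
      base:
        family: quadrant_bars
        uid: bars_axial_a
        params:
          orientations:
          - 0.0
          - 90.0
          - 90.0
          - 0.0
          counts:
          - 1.0
          - 1.0
          - 1.0
          - 1.0
  spiral_cw:
    family: spiral_disc
    uid: spiral_cw
    params:
      n_arms: 4.0
      twist: 360.0
      handedness: 1.0
  spiral_ccw:
    family: mirror
    uid: spiral_ccw
    params:
      base:
        family: spiral_disc
        uid: spiral_cw
        params:
          n_arms: 4.0
          twist: 360.0
          handedness: 1.0
  bars_axial_b:
    family: quadrant_bars
    uid: bars_axial_b
    params:
      orientations:
      - 90.0
      - 90.0
      - 0.0
      - 0.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
  bars_axial_b_rev:
    family: mirror
    uid: bars_axial_b_rev
    params:
      base:
        family: quadrant_bars
        uid: bars_axial_b
        params:
          orientations:
          - 90.0
          - 90.0
          - 0.0
          - 0.0
          counts:
          - 2.0
          - 2.0
          - 2.0
          - 2.0
  octagon_ring:
    family: octagon
    uid: octagon_ring
    params:
      rotation: 0.0
  octagon_ring_rot:
    family: octagon
    uid: octagon_ring_rot
    params:
      rotation: 22.5
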
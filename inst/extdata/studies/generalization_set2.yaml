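study_id: generalization_set2
experiments:
- id: simple_generalization_1
  cs_set:
  - setA_1
  - setA_2
  - setA_3
  - setA_4
  - setA_5
  - setA_6
  reciprocal_set:
  - setB_1
  - setB_2
  - setB_3
  - setB_4
  - setB_5
  - setB_6
  cor: novelA_1
  inc: novelB_1
  bee_pct: 72.0
- id: simple_generalization_2
  cs_set:
  - setA_1
  - setA_2
  - setA_3
  - setA_4
  - setA_5
  - setA_6
  reciprocal_set:
  - setB_1
  - setB_2
  - setB_3
  - setB_4
  - setB_5
  - setB_6
  cor: novelA_2
  inc: novelB_2
  bee_pct: 68.0
- id: simple_generalization_3
  cs_set:
  - setA_1
  - setA_2
  - setA_3
  - setA_4
  - setA_5
  - setA_6
  reciprocal_set:
  - setB_1
  - setB_2
  - setB_3
  - setB_4
  - setB_5
  - setB_6
  cor: novelA_3
  inc: novelB_3
  bee_pct: 70.0
- id: original_vs_reversal
  cs_set:
  - setA_1
  - setA_2
  - setA_3
  - setA_4
  - setA_5
  - setA_6
  reciprocal_set:
  - setB_1
  - setB_2
  - setB_3
  - setB_4
  - setB_5
  - setB_6
  cor: protoA
  inc: protoA_rev
  reciprocal_cor: protoB
  reciprocal_inc: protoB_rev
  bee_pct: 69.0
- id: original_vs_checkerboard
  cs_set:
  - setA_1
  - setA_2
  - setA_3
  - setA_4
  - setA_5
  - setA_6
  reciprocal_set:
  - setB_1
  - setB_2
  - setB_3
  - setB_4
  - setB_5
  - setB_6
  cor: protoA
  inc: checker25
  reciprocal_cor: protoB
  reciprocal_inc: checker25
  bee_pct: 65.0
recipes:
  setA_1:
    family: quadrant_bars
    uid: setA_1
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 56.0
      bar_width: 10.0
  setA_2:
    family: quadrant_bars
    uid: setA_2
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 56.0
      bar_width: 10.0
  setA_3:
    family: quadrant_bars
    uid: setA_3
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 1.0
      - 2.0
      - 1.0
      - 2.0
      bar_length: 56.0
      bar_width: 10.0
  setA_4:
    family: quadrant_bars
    uid: setA_4
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 2.0
      - 1.0
      - 2.0
      - 1.0
      bar_length: 56.0
      bar_width: 10.0
  setA_5:
    family: quadrant_bars
    uid: setA_5
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 70.0
      bar_width: 14.0
  setA_6:
    family: quadrant_bars
    uid: setA_6
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 44.0
      bar_width: 8.0
      spacing: 24.0
  setB_1:
    family: quadrant_bars
    uid: setB_1
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 56.0
      bar_width: 10.0
  setB_2:
    family: quadrant_bars
    uid: setB_2
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 56.0
      bar_width: 10.0
  setB_3:
    family: quadrant_bars
    uid: setB_3
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 1.0
      - 2.0
      - 1.0
      - 2.0
      bar_length: 56.0
      bar_width: 10.0
  setB_4:
    family: quadrant_bars
    uid: setB_4
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 2.0
      - 1.0
      - 2.0
      - 1.0
      bar_length: 56.0
      bar_width: 10.0
  setB_5:
    family: quadrant_bars
    uid: setB_5
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 70.0
      bar_width: 14.0
  setB_6:
    family: quadrant_bars
    uid: setB_6
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 44.0
      bar_width: 8.0
      spacing: 24.0
  novelA_1:
    family: quadrant_bars
    uid: novelA_1
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 3.0
      - 3.0
      - 3.0
      - 3.0
      bar_length: 40.0
      bar_width: 8.0
  novelB_1:
    family: quadrant_bars
    uid: novelB_1
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 3.0
      - 3.0
      - 3.0
      - 3.0
      bar_length: 40.0
      bar_width: 8.0
  novelA_2:
    family: quadrant_bars
    uid: novelA_2
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 64.0
      bar_width: 16.0
  novelB_2:
    family: quadrant_bars
    uid: novelB_2
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 64.0
      bar_width: 16.0
  novelA_3:
    family: quadrant_bars
    uid: novelA_3
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 60.0
      bar_width: 6.0
      spacing: 16.0
  novelB_3:
    family: quadrant_bars
    uid: novelB_3
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 2.0
      - 2.0
      - 2.0
      - 2.0
      bar_length: 60.0
      bar_width: 6.0
      spacing: 16.0
  protoA:
    family: quadrant_bars
    uid: protoA
    params:
      orientations:
      - 45.0
      - 90.0
      - 0.0
      - 135.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 60.0
      bar_width: 12.0
  protoB:
    family: quadrant_bars
    uid: protoB
    params:
      orientations:
      - 135.0
      - 0.0
      - 90.0
      - 45.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 60.0
      bar_width: 12.0
  protoA_rev:
    family: quadrant_bars
    uid: protoA_rev
    params:
      orientations:
      - 0.0
      - 135.0
      - 45.0
      - 90.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 60.0
      bar_width: 12.0
  protoB_rev:
    family: quadrant_bars
    uid: protoB_rev
    params:
      orientations:
      - 90.0
      - 45.0
      - 135.0
      - 0.0
      counts:
      - 1.0
      - 1.0
      - 1.0
      - 1.0
      bar_length: 60.0
      bar_width: 12.0
  checker25:
    family: checkerboard
    uid: checker25
    params:
      check_size: 25.0
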
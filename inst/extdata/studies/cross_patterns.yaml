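study_id: cross_patterns
experiments:
- id: cross90_vs_rot45
  cs: cross90_0
  cor: cross90_0
  inc: cross90_45
  bee_pct: 50.0
- id: cross22_vs_rot90
  cs: cross22_0
  cor: cross22_0
  inc: cross22_90
  bee_pct: 75.0
recipes:
  cross90_0:
    family: cross
    uid: cross90_0
    params:
      rotation: 0.0
  cross90_45:
    family: cross
    uid: cross90_45
    params:
      rotation: 45.0
  cross22_0:
    family: cross
    uid: cross22_0
    params:
      rotation: 0.0
      opening: 22.5
  cross22_90:
    family: cross
    uid: cross22_90
    params:
      rotation: 90.0
      opening: 22.5
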
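binding:
  PTB: PTB
  nPTB: nPTB
  miRs: miR-124
  RESTc: REST
  Ascl1: Ascl1
anchors:
  stage:
  - fibroblast
  - rest_kd
  - conversion
  - conversion
  - conversion
  - conversion
  - conversion
  - conversion
  - conversion
  - conversion
  time_h:
  - 0.0
  - 72.0
  - 8.0
  - 24.0
  - 48.0
  - 72.0
  - 120.0
  - 168.0
  - 336.0
  - 504.0
normalization:
  baseline: 1.0
  ascl1_unit: detection limit
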
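nodes:
- PTB
- nPTB
- miRs
- RESTc
- Ascl1
edges:
- source: miRs
  target: PTB
  sign: inhibition
- source: miRs
  target: nPTB
  sign: inhibition
- source: PTB
  target: nPTB
  sign: inhibition
- source: miRs
  target: RESTc
  sign: inhibition
- source: PTB
  target: RESTc
  sign: activation
- source: RESTc
  target: miRs
  sign: inhibition
- source: RESTc
  target: Ascl1
  sign: inhibition
- source: nPTB
  target: PTB
  sign: activation
inputs:
- input: RESTi
  target: RESTc
  sign: inhibition
- input: vAscl1
  target: miRs
  sign: activation
beta_nodes:
- PTB
- miRs
- RESTc
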
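label: trifurcation_example
demes:
- name: CI
  size: 50000.0
  growth: 0.0
- name: CII
  size: 150000.0
  growth: 0.0
- name: CIII
  size: 160000.0
  growth: 0.0
- name: ANC
  size: 160000.0
  growth: 0.0
events:
- time: 204300.0
  type: merge
  from: CI
  to: ANC
  value: .na.real
- time: 204300.0
  type: merge
  from: CII
  to: ANC
  value: .na.real
- time: 204300.0
  type: merge
  from: CIII
  to: ANC
  value: .na.real
migration: ~
samples:
  CI: 82
  CII: 97
  CIII: 87
  ANC: 0
loci:
- name: nodA
  length: 535
  mu: 1.0e-08
- name: nodC
  length: 798
  mu: 1.0e-08
- name: nifA
  length: 693
  mu: 1.0e-08
- name: nifH
  length: 686
  mu: 1.0e-08
- name: nolT
  length: 596
  mu: 1.0e-08
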
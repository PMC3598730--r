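# 18-process EGF-insulin crosstalk model; kinetic values are SYNTHETIC
# (chosen to reproduce the documented qualitative behaviour; see ?buildEgfInsulin)
molecules:
- name: ins
  sites:
  - b1
- name: ir
  sites:
  - b_ins
  - b_ins2
  - p1
  - p2
- name: shc
  sites:
  - b_ir
  - p1
- name: grb2
  sites:
  - b_shc
  - b_sos
- name: sos
  sites:
  - b_grb2
- name: irs
  sites:
  - b_ir
  - p1
  - p2
- name: pi3k
  sites:
  - b_irs
- name: egf
  sites:
  - b1
- name: egfr
  sites:
  - b_egf
  - d
  - p1
  - p2
processes:
- id: 1
  type: binding
  sites:
  - ins.b1
  - ir.b_ins
  reversible: yes
- id: 2
  type: binding
  sites:
  - ins.b1
  - ir.b_ins2
  reversible: yes
- id: 3
  type: modification
  sites:
  - ir.p1
  reversible: yes
- id: 4
  type: modification
  sites:
  - ir.p2
  reversible: yes
- id: 5
  type: binding
  sites:
  - shc.b_ir
  - ir.p1
  reversible: yes
- id: 6
  type: modification
  sites:
  - shc.p1
  reversible: yes
- id: 7
  type: binding
  sites:
  - grb2.b_shc
  - shc.p1
  reversible: yes
- id: 8
  type: binding
  sites:
  - sos.b_grb2
  - grb2.b_sos
  reversible: yes
- id: 9
  type: binding
  sites:
  - irs.b_ir
  - ir.p2
  reversible: yes
- id: 10
  type: modification
  sites:
  - irs.p1
  reversible: yes
- id: 11
  type: modification
  sites:
  - irs.p2
  reversible: yes
- id: 12
  type: binding
  sites:
  - pi3k.b_irs
  - irs.p2
  reversible: yes
- id: 13
  type: binding
  sites:
  - egf.b1
  - egfr.b_egf
  reversible: yes
- id: 14
  type: homodimerization
  sites:
  - egfr.d
  reversible: yes
- id: 15
  type: modification
  sites:
  - egfr.p1
  reversible: yes
- id: 16
  type: modification
  sites:
  - egfr.p2
  reversible: yes
- id: 17
  type: binding
  sites:
  - shc.b_ir
  - egfr.p1
  reversible: yes
- id: 18
  type: binding
  sites:
  - grb2.b_shc
  - egfr.p2
  reversible: yes
influences:
- source: 1
  target: 2
  kind: plain
- source: 1
  target: 3
  kind: plain
- source: 1
  target: 4
  kind: plain
- source: 2
  target: 1
  kind: plain
- source: 2
  target: 3
  kind: plain
- source: 2
  target: 4
  kind: plain
- source: 3
  target: 5
  kind: all_or_none
- source: 4
  target: 9
  kind: all_or_none
- source: 5
  target: 6
  kind: plain
- source: 6
  target: 7
  kind: all_or_none
- source: 7
  target: 8
  kind: plain
- source: 9
  target: 10
  kind: plain
- source: 9
  target: 11
  kind: plain
- source: 11
  target: 12
  kind: all_or_none
- source: 13
  target: 14
  kind: plain
- source: 14
  target: 13
  kind: plain
- source: 14
  target: 15
  kind: plain
- source: 14
  target: 16
  kind: plain
- source: 15
  target: 17
  kind: all_or_none
- source: 16
  target: 18
  kind: all_or_none
- source: 17
  target: 6
  kind: plain
parameters:
- node: 1
  rows:
  - ctx:
    - 0
    kfw: 0.25
    kbw: 1.0
  - ctx:
    - 1
    kfw: 0.1
    kbw: 1.0
- node: 2
  rows:
  - ctx:
    - 0
    kfw: 0.25
    kbw: 1.0
  - ctx:
    - 1
    kfw: 0.1
    kbw: 1.0
- node: 3
  rows:
  - ctx:
    - 0
    - 0
    kfw: 0.001
    kbw: 1.0
  - ctx:
    - 0
    - 1
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 0
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 4
  rows:
  - ctx:
    - 0
    - 0
    kfw: 0.001
    kbw: 1.0
  - ctx:
    - 0
    - 1
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 0
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 5
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 6
  rows:
  - ctx:
    - 0
    - 0
    kfw: 0.01
    kbw: 1.0
  - ctx:
    - 0
    - 1
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 0
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    - 1
    'y': '1'
- node: 7
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 8
  rows:
  - ctx:
    - 0
    kfw: 0.01
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 9
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 10
  rows:
  - ctx:
    - 0
    kfw: 0.01
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 11
  rows:
  - ctx:
    - 0
    kfw: 0.01
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 12
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 13
  rows:
  - ctx:
    - 0
    kfw: 0.1
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 14
  rows:
  - ctx:
    - 0
    - 0
    kfw: 0.001
    kbw: 1.0
  - ctx:
    - 0
    - 1
    kfw: 0.01
    kbw: 1.0
  - ctx:
    - 1
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 15
  rows:
  - ctx:
    - 0
    kfw: 0.001
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 16
  rows:
  - ctx:
    - 0
    kfw: 0.001
    kbw: 1.0
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 17
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
- node: 18
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
thresholds:
  t1: 0.01
  t2: 0.1

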
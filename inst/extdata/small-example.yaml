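# Four-process teaching example (see ?buildSmallExample)
molecules:
- name: A
  sites:
  - b1
- name: B
  sites:
  - b1
- name: R
  sites:
  - b1
  - p1
  - p2
processes:
- id: 1
  type: binding
  sites:
  - A.b1
  - R.b1
  reversible: yes
- id: 2
  type: modification
  sites:
  - R.p1
  reversible: yes
- id: 3
  type: modification
  sites:
  - R.p2
  reversible: yes
- id: 4
  type: binding
  sites:
  - B.b1
  - R.p1
  reversible: yes
influences:
- source: 1
  target: 2
  kind: plain
- source: 2
  target: 3
  kind: plain
- source: 2
  target: 4
  kind: all_or_none
- source: 3
  target: 2
  kind: plain
parameters:
- node: 1
  rows:
  - ctx: []
    kfw: 1.0
    kbw: 1.0
- node: 2
  rows:
  - ctx:
    - 0
    - 0
    kfw: 1.0
    kbw: 100.0
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
- node: 3
  rows:
  - ctx:
    - 0
    kfw: 1.0
    kbw: 1.0
  - ctx:
    - 1
    kfw: 2.0
    kbw: 1.0
- node: 4
  rows:
  - ctx:
    - 1
    kfw: 1.0
    kbw: 1.0
thresholds:
  t1: 0.01
  t2: 0.1

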
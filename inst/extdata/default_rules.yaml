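# Default phenotype gates: highest-priority satisfied rule wins.
# CK- requirements exclude tumor cells from immune gates.
- name: tumor
  positive: [CK]
  priority: 100
- name: Treg
  positive: [CD3, FoxP3]
  negative: [CD8, CK]
  priority: 90
- name: cytotoxic_T
  positive: [CD3, CD8]
  negative: [CK]
  priority: 80
- name: helper_T
  positive: [CD3]
  negative: [CD8, CK]
  priority: 70
- name: PD1_T
  positive: [CD3, PD1]
  negative: [CK]
  priority: 60
- name: FoxP3neg_T
  positive: [CD3]
  negative: [FoxP3, CK]
  priority: 50
- name: B_cell
  positive: [CD20]
  negative: [CK]
  priority: 40
- name: macrophage
  positive: [CD68]
  negative: [CK]
  priority: 30
- name: NK
  positive: [CD56]
  negative: [CK]
  priority: 20
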
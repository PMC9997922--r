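dispersal:
- 1
- 5
autocorrelation: 75.0
selection: 0.1
gap_permeability: 0.7
horizon: 4000
gap_edges: 1.0
habitat_A:
- 1
- 4
- 6
habitat_B:
- 2
- 3
- 5
snapshot_steps:
- 1000
- 2000
- 3000
- 4000
allele_log_every: 50
replicates: 10
base_seed: 1
demography:
  s_juv: 0.5
  s_adult: 0.885
  resource_threshold: 0.2
  resource_penalty: 0.1
  resource_goal: 2.5
  fecundity_max: 1.2
  fecundity_sd: 0.5
  pairing_radius: 3.0
epochs:
- name: continuous
  start: 1.0
  end: 1000.0
  barrier: none
  gap_permeability: 0.0
  selection: 0.0
  habitat: no
- name: isolated
  start: 1001.0
  end: 2000.0
  barrier: absolute
  gap_permeability: 0.0
  selection: 0.0
  habitat: no
- name: semi_connected
  start: 2001.0
  end: 3000.0
  barrier: gapped
  gap_permeability: 0.7
  selection: 0.0
  habitat: no
- name: semi_connected_selection
  start: 3001.0
  end: 4000.0
  barrier: gapped
  gap_permeability: 0.7
  selection: 0.1
  habitat: yes
loci:
- locus: 1
  allele: 1
  freq: 0.2
  adaptation: neutral
- locus: 1
  allele: 2
  freq: 0.2
  adaptation: neutral
- locus: 1
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 1
  allele: 4
  freq: 0.2
  adaptation: neutral
- locus: 1
  allele: 5
  freq: 0.2
  adaptation: neutral
- locus: 2
  allele: 1
  freq: 0.3
  adaptation: neutral
- locus: 2
  allele: 2
  freq: 0.25
  adaptation: neutral
- locus: 2
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 2
  allele: 4
  freq: 0.15
  adaptation: neutral
- locus: 2
  allele: 5
  freq: 0.1
  adaptation: neutral
- locus: 3
  allele: 1
  freq: 0.1
  adaptation: neutral
- locus: 3
  allele: 2
  freq: 0.15
  adaptation: neutral
- locus: 3
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 3
  allele: 4
  freq: 0.25
  adaptation: neutral
- locus: 3
  allele: 5
  freq: 0.3
  adaptation: neutral
- locus: 4
  allele: 1
  freq: 0.01
  adaptation: neutral
- locus: 4
  allele: 2
  freq: 0.04
  adaptation: neutral
- locus: 4
  allele: 3
  freq: 0.15
  adaptation: neutral
- locus: 4
  allele: 4
  freq: 0.3
  adaptation: neutral
- locus: 4
  allele: 5
  freq: 0.5
  adaptation: neutral
- locus: 5
  allele: 1
  freq: 0.5
  adaptation: neutral
- locus: 5
  allele: 2
  freq: 0.3
  adaptation: neutral
- locus: 5
  allele: 3
  freq: 0.15
  adaptation: neutral
- locus: 5
  allele: 4
  freq: 0.04
  adaptation: neutral
- locus: 5
  allele: 5
  freq: 0.01
  adaptation: neutral
- locus: 6
  allele: 1
  freq: 0.2
  adaptation: neutral
- locus: 6
  allele: 2
  freq: 0.2
  adaptation: A
- locus: 6
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 6
  allele: 4
  freq: 0.2
  adaptation: B
- locus: 6
  allele: 5
  freq: 0.2
  adaptation: neutral
- locus: 7
  allele: 1
  freq: 0.3
  adaptation: neutral
- locus: 7
  allele: 2
  freq: 0.25
  adaptation: neutral
- locus: 7
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 7
  allele: 4
  freq: 0.15
  adaptation: neutral
- locus: 7
  allele: 5
  freq: 0.1
  adaptation: A
- locus: 8
  allele: 1
  freq: 0.1
  adaptation: neutral
- locus: 8
  allele: 2
  freq: 0.15
  adaptation: neutral
- locus: 8
  allele: 3
  freq: 0.2
  adaptation: neutral
- locus: 8
  allele: 4
  freq: 0.25
  adaptation: neutral
- locus: 8
  allele: 5
  freq: 0.3
  adaptation: B
- locus: 9
  allele: 1
  freq: 0.01
  adaptation: A
- locus: 9
  allele: 2
  freq: 0.04
  adaptation: neutral
- locus: 9
  allele: 3
  freq: 0.15
  adaptation: neutral
- locus: 9
  allele: 4
  freq: 0.3
  adaptation: neutral
- locus: 9
  allele: 5
  freq: 0.5
  adaptation: neutral
- locus: 10
  allele: 1
  freq: 0.5
  adaptation: B
- locus: 10
  allele: 2
  freq: 0.3
  adaptation: neutral
- locus: 10
  allele: 3
  freq: 0.15
  adaptation: neutral
- locus: 10
  allele: 4
  freq: 0.04
  adaptation: neutral
- locus: 10
  allele: 5
  freq: 0.01
  adaptation: neutral
patches:
- patch_id: 1
  label: L1
  cols: 26
  rows: 51
  col0: 0
  row0: 0
- patch_id: 2
  label: L2
  cols: 26
  rows: 51
  col0: 26
  row0: 0
- patch_id: 3
  label: M1
  cols: 10
  rows: 20
  col0: -10
  row0: 15
- patch_id: 4
  label: M2
  cols: 10
  rows: 20
  col0: 52
  row0: 15
- patch_id: 5
  label: S1
  cols: 5
  rows: 10
  col0: -5
  row0: 40
- patch_id: 6
  label: S2
  cols: 5
  rows: 10
  col0: 52
  row0: 0
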
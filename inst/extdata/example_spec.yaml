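# Small synthetic-cohort specification: a hub node tied to three spokes plus
# one spoke-spoke edge. target partial correlations as an edge list.
phenotypes: [hub, s1, s2, s3]
K: 2000
seed: 42
edges:
  - {node1: hub, node2: s1, omega: 0.45}
  - {node1: hub, node2: s2, omega: -0.30}
  - {node1: hub, node2: s3, omega: 0.20}
  - {node1: s1, node2: s2, omega: 0.15}
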
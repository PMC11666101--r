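{
  "name": "complex biantennary, core fucose, one terminal Neu5Ac",
  "comment": "Representative mature N-glycan used for channel-surface modeling. Core: Asn-GlcNAc(+Fuc a1-6)-GlcNAc-Man branching a1-3/a1-6; each arm GlcNAc-Gal; the a1-3 arm capped by Neu5Ac a2-6 (default linkage; edit to a2-3 if preferred).",
  "nodes": [
    {"id": "G1", "sugar": "GlcNAc"},
    {"id": "F1", "sugar": "Fuc"},
    {"id": "G2", "sugar": "GlcNAc"},
    {"id": "M1", "sugar": "Man"},
    {"id": "M2", "sugar": "Man"},
    {"id": "M3", "sugar": "Man"},
    {"id": "G3", "sugar": "GlcNAc"},
    {"id": "G4", "sugar": "GlcNAc"},
    {"id": "L1", "sugar": "Gal"},
    {"id": "L2", "sugar": "Gal"},
    {"id": "S1", "sugar": "Neu5Ac"}
  ],
  "linkages": [
    {"parent": "G1", "child": "F1", "anomeric": "alpha", "donor": 1, "acceptor": 6},
    {"parent": "G1", "child": "G2", "anomeric": "beta",  "donor": 1, "acceptor": 4},
    {"parent": "G2", "child": "M1", "anomeric": "beta",  "donor": 1, "acceptor": 4},
    {"parent": "M1", "child": "M2", "anomeric": "alpha", "donor": 1, "acceptor": 3},
    {"parent": "M1", "child": "M3", "anomeric": "alpha", "donor": 1, "acceptor": 6},
    {"parent": "M2", "child": "G3", "anomeric": "beta",  "donor": 1, "acceptor": 2},
    {"parent": "M3", "child": "G4", "anomeric": "beta",  "donor": 1, "acceptor": 2},
    {"parent": "G3", "child": "L1", "anomeric": "beta",  "donor": 1, "acceptor": 4},
    {"parent": "G4", "child": "L2", "anomeric": "beta",  "donor": 1, "acceptor": 4},
    {"parent": "L1", "child": "S1", "anomeric": "alpha", "donor": 2, "acceptor": 6}
  ]
}
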
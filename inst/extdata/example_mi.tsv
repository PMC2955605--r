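gene	G1	G2	G3	G4
G1	0.00000000000000000	0.69999999999999996	0.90000000000000002	0.80000000000000004
G2	0.69999999999999996	0.00000000000000000	0.59999999999999998	0.50000000000000000
G3	0.90000000000000002	0.59999999999999998	0.00000000000000000	0.10000000000000001
G4	0.80000000000000004	0.50000000000000000	0.10000000000000001	0.00000000000000000
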
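# chemotaxis phosphotransfer network parameters
k1: 0.12  # s^-1, CheA2 autophosphorylation
k2: 0.98  # s^-1, CheA3 phosphorylation by CheA4
k10: 0.0193  # s^-1, CheY3-P autodephosphorylation
k11: 0.0182  # s^-1, CheY4-P autodephosphorylation
k12: 0.169  # s^-1, CheY6-P autodephosphorylation
k13: 0.000173  # s^-1, CheB1-P autodephosphorylation
k14: 0.0133  # s^-1, CheB2-P autodephosphorylation
k3: 6600  # (M s)^-1, CheA2-P -> CheY3
k3r: 11700  # (M s)^-1, CheY3-P -> CheA2
k4: 885000  # (M s)^-1, CheA2-P -> CheY4
k4r: 232000  # (M s)^-1, CheY4-P -> CheA2
k5: 1540  # (M s)^-1, CheA2-P -> CheY6
k5r: 0  # (M s)^-1, CheY6-P -> CheA2 (zero)
k6: 1780000  # (M s)^-1, CheA2-P -> CheB1
k6r: 2850000  # (M s)^-1, CheB1-P -> CheA2
k7: 3070  # (M s)^-1, CheA2-P -> CheB2
k7r: 1530  # (M s)^-1, CheB2-P -> CheA2
k8: 775000  # (M s)^-1, CheA3-P -> CheY6
k8r: 2830  # (M s)^-1, CheY6-P -> CheA3
k9: 61500  # (M s)^-1, CheA3-P -> CheB2
k9r: 3100  # (M s)^-1, CheB2-P -> CheA3
k15a: 5200  # (M s)^-1, CheY6-P dephosphorylation by CheA3
k15b: 5200  # (M s)^-1, CheY6-P dephosphorylation by CheA3-P
A2T: 89.9  # uM, total CheA2
A3T: 89.9  # uM, total CheA3
Y3T: 3.5  # uM, total CheY3
Y4T: 13.8  # uM, total CheY4
Y6T: 225  # uM, total CheY6
B1T: 81.2  # uM, total CheB1
B2T: 20.8  # uM, total CheB2
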
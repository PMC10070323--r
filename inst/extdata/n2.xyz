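2
nitrogen molecule near equilibrium (bond 1.1112 Angstrom = 2.1 bohr)
N 0.0 0.0 0.0
N 0.0 0.0 1.1112
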
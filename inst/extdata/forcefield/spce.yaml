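model: spce
kind: water
comment: SPC/E oxygen Lennard-Jones site (0.1553 kcal/mol, 3.166 A).
sites:
  - name: O
    epsilon_kJmol: 0.6497752
    sigma_nm: 0.3166
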
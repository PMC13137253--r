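model: opc
kind: water
comment: OPC oxygen Lennard-Jones site (0.2128 kcal/mol, 3.16655 A).
sites:
  - name: O
    epsilon_kJmol: 0.8903552
    sigma_nm: 0.316655
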
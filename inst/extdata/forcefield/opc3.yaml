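model: opc3
kind: water
comment: OPC3 oxygen Lennard-Jones site (0.163406 kcal/mol, 3.17427 A).
sites:
  - name: O
    epsilon_kJmol: 0.68369
    sigma_nm: 0.317427
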
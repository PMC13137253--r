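model: tip4p2005
kind: water
comment: TIP4P/2005 oxygen Lennard-Jones site (93.2 K, 3.1589 A).
sites:
  - name: O
    epsilon_over_kB_K: 93.2
    sigma_nm: 0.31589
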
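model: trappe_ua
kind: alkane
comment: >-
  TraPPE united-atom alkane Lennard-Jones site parameters; standard published
  constants shipped as inputs.
sites:
  - name: CH4
    epsilon_over_kB_K: 148.0
    sigma_nm: 0.373
  - name: CH3
    epsilon_over_kB_K: 98.0
    sigma_nm: 0.375
  - name: CH2
    epsilon_over_kB_K: 46.0
    sigma_nm: 0.395
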
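model: hh_alkane
kind: alkane_water_pairs
water: tip4p2005
comment: >-
  HH-alkane cross well depths with TIP4P/2005 water. Only the well depths are
  published in the tables this package transcribes; the HH-alkane sigma values
  (set by fixing the thermal radius at 300 K) are not, so sigma is left null
  and must be supplied by the user for any distance-dependent calculation.
pairs:
  - name: "CH4:O"
    epsilon_kJmol: 0.9765
    epsilon_updated_kJmol: 1.0226
    sigma_nm: null
  - name: "CH3:O"
    epsilon_kJmol: 0.7946
    epsilon_updated_kJmol: 0.8224
    sigma_nm: null
  - name: "CH2:O"
    epsilon_kJmol: 0.5444
    epsilon_updated_kJmol: 0.5652
    sigma_nm: null
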
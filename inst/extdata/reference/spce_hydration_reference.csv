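n_carbons,dg_hyd_exp,dg_hyd_model,dg_cavity,dh_att_model,dg_hyd_sim,provenance
1,8.37,9.39,24.52,-15.12,8.53,experiment
2,7.66,9.28,34.87,-25.59,7.57,experiment
3,8.18,9.94,43.85,-33.91,8.47,experiment
4,8.70,11.16,52.55,-41.39,8.89,experiment
5,9.76,12.19,61.86,-49.67,,experiment
6,10.4,13.11,70.34,-57.23,10.34,experiment
8,12.1,15.69,87.72,-72.03,,experiment
10,13.32,18.08,105.75,-87.68,13.47,group_contribution
12,14.80,20.15,123.36,-103.21,,group_contribution
14,16.28,22.95,140.80,-117.85,17.34,group_contribution
16,17.76,25.15,157.81,-132.66,,group_contribution
18,19.24,27.64,174.72,-147.08,19.90,group_contribution
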
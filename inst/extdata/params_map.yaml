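delta_mRNA: '0.006'
delta_prot: '0.003'
nu_mRNA:
  Cyp19: 3e-10
  Hsd17b1: 6e-10
  Hsd17b2: '4.2e-11'
nu_prot:
  Cyp19: 6e+03
  Hsd17b1: '6.3e+03'
  Hsd17b2: 6e+03
mRNA0:
  Cyp19: '4.96e-08'
  Hsd17b1: '1.03e-07'
  Hsd17b2: 7e-09
prot0:
  Cyp19: '0.1'
  Hsd17b1: '0.21'
  Hsd17b2: '0.014'
lambda:
  Cyp19_A: '1.07e-07'
  Hsd17b1_A: '5.65e-08'
  Hsd17b2_T: '6.65e-08'
  Cyp19_T: '2.67e-07'
  Hsd17b1_E1: '1.78e-05'
  Hsd17b2_E2: '7.91e-08'
xi:
  Cyp19_A: '8.25e-09'
  Hsd17b1_A: '4.84e-05'
  Hsd17b2_T: '5.67e-06'
  Cyp19_T: '1.24e-08'
  Hsd17b1_E1: '1.3e-06'
  Hsd17b2_E2: '5.4e-06'
kappa:
  Cyp19: '2.08e+06'
  Hsd17b1: '6.04e+05'
R_oi:
  A: '0.0124'
  T: '0.013'
  E1: '0.0084'
  E2: '0.0108'
  FSH: '1'
K_out:
  A: 1e-08
  T: 1e-08
  E1: 1e-08
  E2: 1e-08
  FSH: 1e-08
V_GC: '2.7e-10'
F_ov: '0.2654'
V_ov_diestrus: '0.05'
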
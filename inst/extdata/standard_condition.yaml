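name: standard_nitrogen_fixation
bounds:
  EX_mal__L_e:
  - -1.44
  - 1000.0
  EX_succ_e:
  - -1.38
  - 1000.0
  EX_glu__L_e:
  - -0.18
  - 1000.0
  EX_o2_c:
  - -1.26
  - 0.0
  EX_n2_c:
  - -1000.0
  - 0.0
  EX_h_c:
  - -1000.0
  - 1000.0
  EX_h2o_c:
  - -1000.0
  - 1000.0
  EX_pi_c:
  - -1000.0
  - 1000.0
  EX_fe2_e:
  - -1000.0
  - 0.0
  EX_nh4_e:
  - 0.0
  - 1000.0
  EX_ala__L_e:
  - 0.0
  - 1000.0
  EX_asp__L_e:
  - 0.0
  - 1000.0
  EX_co2_c:
  - 0.0
  - 1000.0
  EX_h2_c:
  - 0.0
  - 1000.0
  ATPM:
  - 4.0
  - 4.0
  EX_inost_e:
  - -0.05
  - 1000.0
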
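# Rifampin (strong CYP3A4 inducer; validation perpetrator). Curated
# literature parameter set (synthetic curation). Induction parameters
# IndMax/IndC50 in the standard Emax form on enzyme synthesis.
schema_version: 1
name: rifampin
molecular_weight: 822.94
logP: 2.7
pKa_list: [7.9]
compound_type: monoprotic base
blood_plasma_ratio: 0.9
fu_plasma: 0.15
fa: 0.95
ka: 1.0
fu_gut: 1.0
kp_scalar: 1.0
vss_target: 0.7         # L/kg
clpo: 19.0              # L/h
retrograde:
  fm:
    CYP3A4: 0.25
  fa: 0.95
renal_cl: 1.5
interaction_set:
  - {target: CYP3A4, mechanism: induction, ind_max: 16.0, ind_c50: 0.32}
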
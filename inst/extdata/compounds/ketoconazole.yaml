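# Ketoconazole (strong reversible CYP3A4 inhibitor; validation
# perpetrator). Curated literature parameter set (synthetic curation).
schema_version: 1
name: ketoconazole
molecular_weight: 531.43
logP: 4.04
pKa_list: [6.5, 2.9]
compound_type: diprotic base
blood_plasma_ratio: 0.62
fu_plasma: 0.029
fa: 0.85
ka: 1.2
fu_gut: 1.0
kp_scalar: 1.0
vss_target: 0.9         # L/kg
clpo: 8.0               # L/h
retrograde:
  fm:
    CYP3A4: 0.95
  fa: 0.85
renal_cl: 0.1
interaction_set:
  - {target: CYP3A4, mechanism: reversible, ki: 0.015}
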
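# Simvastatin (CYP3A4 victim used in model validation). Library-style
# record; the per-pmol CYP3A4 CLint is the unadjusted library value -
# apply scale_library_clearance(record, 0.6) to reproduce the 40%
# reduction fitted to clinical oral-clearance data (2284 -> 1370.4 and
# 254 -> 152.4 uL/min). Other fields are curated literature values
# (synthetic curation).
schema_version: 1
name: simvastatin
molecular_weight: 418.57
logP: 4.68
pKa_list: []
compound_type: neutral
blood_plasma_ratio: 0.56
fu_plasma: 0.02
fa: 0.85
ka: 1.0
fu_gut: 0.155
gut_cyp3a4: true
clu_int_gut: 150.0      # L/h unbound enteric CYP3A4 intrinsic clearance
kp_scalar: 1.0
vss_target: 1.3         # L/kg
cyp_clint:
  CYP3A4: 2284.0        # uL/min/pmol (library value before the 40% reduction)
additional_hlm_clint: 254.0  # uL/min/mg (library value before reduction)
renal_cl: 0.0
interaction_set: []
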
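# Rosuvastatin (OATP1B1/1B3 victim). Curated literature parameter set
# (synthetic curation): fu 0.12, B/P 0.69, fa ~0.5, renal clearance
# ~28% of total (~14 L/h), hepatic elimination rate-limited by OATP
# uptake; uptake CLint sized for hepatic plasma clearance ~35 L/h.
schema_version: 1
name: rosuvastatin
molecular_weight: 481.54
logP: 0.13
pKa_list: [4.6]
compound_type: monoprotic acid
blood_plasma_ratio: 0.69
fu_plasma: 0.12
fa: 0.5
ka: 0.6
fu_gut: 1.0
kp_scalar: 1.0
vss_target: 1.7         # L/kg
renal_cl: 13.7          # L/h
hepatic_uptake:         # L/h unbound sinusoidal uptake intrinsic clearance
  OATP1B1: 427.0
  OATP1B3: 122.0
  passive: 61.0
interaction_set: []
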
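# Pravastatin (OATP1B1/1B3 victim). Curated literature parameter set
# (synthetic curation): hydrophilic acid, fu 0.5, B/P 0.55, low oral
# bioavailability (fa ~0.5), hepatic elimination rate-limited by sinusoidal
# OATP uptake, substantial renal clearance (~24 L/h). Uptake intrinsic
# clearances split OATP1B1-dominant with a small passive component; total
# sized to give hepatic plasma clearance ~35 L/h in this physiology.
schema_version: 1
name: pravastatin
molecular_weight: 424.53
logP: 1.65
pKa_list: [4.7]
compound_type: monoprotic acid
blood_plasma_ratio: 0.55
fu_plasma: 0.5
fa: 0.5
ka: 1.0
fu_gut: 1.0
kp_scalar: 1.0
vss_target: 0.47        # L/kg
renal_cl: 24.0          # L/h
hepatic_uptake:         # L/h unbound sinusoidal uptake intrinsic clearance
  OATP1B1: 122.0
  OATP1B3: 51.0
  passive: 30.0
interaction_set: []
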
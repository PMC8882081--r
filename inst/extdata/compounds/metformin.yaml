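# Metformin (OCT2/MATE victim). Curated literature parameter set
# (synthetic curation - not printed in the modeled study): hydrophilic
# strong base, negligible plasma binding and metabolism; renal clearance
# ~31 L/h dominated by tubular secretion (GFR*fu ~7.2 L/h filtration);
# Vss ~3 L/kg reflecting wide tissue distribution via cation transport;
# oral F ~0.55 with slow absorption (Tmax 2.5-3 h).
# Kidney model: OCT2-mediated basolateral uptake favoured by the
# electrochemical gradient (uptake PS >> efflux PS -> intracellular
# accumulation), proton-coupled MATE apical efflux rate-limiting; MATE PS
# is left null and calibrated so baseline renal CL matches renal_cl.
schema_version: 1
name: metformin
molecular_weight: 129.16
logP: -1.43
pKa_list: [12.4]
compound_type: monoprotic base
blood_plasma_ratio: 1.0
fu_plasma: 0.99
fa: 0.55
ka: 0.7                 # 1/h
fu_gut: 1.0
kp_scalar: 1.0
vss_target: 3.0         # L/kg
renal_cl: 31.0          # L/h reference renal clearance (arterial plasma)
kidney_model:
  ps_oct2: 60.0         # L/h unbound basolateral uptake (EGD multiplier folded in)
  ps_passive: 2.0       # L/h bidirectional passive
  ps_mate: null         # calibrated to renal_cl
  cell_volume: 0.15     # L
  vasc_volume: 0.08     # L
  fu_cell: 1.0
interaction_set: []
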
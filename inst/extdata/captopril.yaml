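# Drug-specific model input parameters for captopril.
# Physicochemistry and PK inputs collected from the published literature;
# vss_per_kg stores the full-precision Rodgers-Rowland prediction (0.267)
# rather than its 2-significant-figure display value.
molecular_weight: 217.29   # g/mol
logp: 0.34                 # octanol-water log partition coefficient
pka: 4.02
ionization_class: monoprotic_acid
ka: 1.75                   # 1/h, first-order absorption rate
tlag: 0.2                  # h, absorption lag time
fa: 0.7                    # fraction absorbed
kin: 0.25                  # 1/h, central -> single adjusting compartment
kout: 0.25                 # 1/h, single adjusting compartment -> central
bp_ratio: 1.0              # blood-to-plasma concentration ratio
fu: 0.73                   # fraction unbound in plasma
vss_per_kg: 0.267          # L/kg, steady-state volume of distribution
cl_iv: 49.5                # L/h, total systemic plasma clearance
cl_r: 22.2                 # L/h, renal plasma clearance
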
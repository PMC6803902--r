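# Default model configuration: volatile phenols in model wine, four-phase
# HS-SPME vial (20 mL vial, 6 mL sample, 0.5 mL internal-standard ampoule,
# PDMS-type fiber coating).
#
# K1: dimensionless liquid/gas Henry partition constant of the sample matrix
#     at the working temperature (guaiacol's literature value is 2.2e4; the
#     other phenols carry order-of-magnitude literature-scale values).
# K2: gas/fiber distribution constant (C_h/C_f); 1e-5 means the coating
#     enriches 1e5-fold over the headspace and holds < 0.1% of the analyte.
# K3: liquid/gas constant of the internal-standard liquid; omitted entries
#     default to K1 (same model-wine matrix).
# quant_ions: SIM quantifier/qualifier m/z values, metadata only.
# Binding constants (kb) are intentionally absent: they are derived at run
# time by inverting the reference retention table (default_binding_constants).

vial:
  V_total: 20.0
  V_s: 6.0
  V_i: 0.5
  V_f: 0.00066

cyclodextrins:
  - name: alpha
    formula: C36H60O30
  - name: beta
    formula: C42H70O35
  - name: gamma
    formula: C48H80O40

compounds:
  - name: guaiacol
    formula: C7H8O2
    K1: 22000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [109, 124]
  - name: 4-methylguaiacol
    formula: C8H10O2
    K1: 25000.0
    K2: 0.00001
    istd: d3-4-methylguaiacol
    quant_ions: [123, 138]
  - name: 4-ethylphenol
    formula: C8H10O
    K1: 14000.0
    K2: 0.00001
    istd: d4-4-ethylphenol
    quant_ions: [77, 122]
  - name: 4-ethylguaiacol
    formula: C9H12O2
    K1: 23000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [122, 137, 152]
  - name: o-cresol
    formula: C7H8O
    K1: 10000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [77, 90, 108]
  - name: m-cresol
    formula: C7H8O
    K1: 17000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [79, 108]
  - name: p-cresol
    formula: C7H8O
    K1: 18000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [77, 107]
  - name: eugenol
    formula: C10H12O2
    K1: 20000.0
    K2: 0.00001
    istd: d3-guaiacol
    quant_ions: [149, 164]

isotopologues:
  - name: d3-guaiacol
    parent: guaiacol
    formula: C7H5D3O2
    quant_ions: [109, 127]
  - name: d3-4-methylguaiacol
    parent: 4-methylguaiacol
    formula: C8H7D3O2
    quant_ions: [126, 141]
  - name: d4-4-ethylphenol
    parent: 4-ethylphenol
    formula: C8H6D4O
    quant_ions: [77, 126]
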
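# Default exp-6 (Buckingham) repulsion-dispersion parameters for organic
# C/H/N/O crystals, Williams-type atom-atom values from the open literature.
# units: A in kJ/mol, B in 1/angstrom, C in kJ*angstrom^6/mol
provenance: "Williams-type exp-6 set for C/H/N/O (open literature values)"
cutoff: 15.0
tail_correction: true
elements:
  C:
    A: 369743.0
    B: 3.60
    C: 2439.8
  H:
    A: 11971.0
    B: 3.74
    C: 136.4
  N:
    A: 254529.2
    B: 3.78
    C: 1378.4
  O:
    A: 230064.3
    B: 3.96
    C: 1123.6
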
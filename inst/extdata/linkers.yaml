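# Built-in cross-linker and Pt adduct chemistry.
# Compositions are net atoms added to the bridged species.
linkers:
  - name: DSG
    light: {C: 5, H: 4, O: 2}
    heavy: {C: 5, D: 4, O: 2}
    reactive: [K, S, nterm]
    span: 20.5
    span_tol: 3.0
  - name: DSS
    light: {C: 8, H: 10, O: 2}
    heavy: {C: 8, H: 6, D: 4, O: 2}
    reactive: [K, S, nterm]
    span: 24.2
    span_tol: 3.0
pt_adduct:
  name: transplatin
  protein_reactive: [C, M, H, T]
  include_termini: false
  dna_reactive: G
  span: 5.0
  span_tol: 2.0
  pt_isotope: 195Pt
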
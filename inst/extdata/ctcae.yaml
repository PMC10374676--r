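# CTCAE v5 grading thresholds for hematologic laboratory toxicities, 1e9/L.
# grade g applies for values in [threshold_g, threshold_{g-1}); values exactly
# on a boundary take the milder grade; grade 0 at or above the LLN.
ctcae:
  ANC: {lln: 1.8, g1: 1.5, g2: 1.0, g3: 0.5}
  PLT: {lln: 150, g1: 75,  g2: 50,  g3: 25}
  WBC: {lln: 4.0, g1: 3.0, g2: 2.0, g3: 1.0}
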
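# Linear compartmental PK models of the cytotoxic drugs.
# central_volume in L, rate constants in 1/day; k13/k31 zero for 2-compartment
# models. Constants give central half-lives of hours; the docetaxel entry is a
# generic 3-compartment placeholder.
pk:
  oxaliplatin:
    n_compartments: 3
    central_volume: 30.0
    k10: 8.0
    k12: 5.0
    k21: 3.0
    k13: 1.2
    k31: 0.3
  fluorouracil:
    n_compartments: 2
    central_volume: 25.0
    k10: 50.0
    k12: 6.0
    k21: 8.0
    k13: 0.0
    k31: 0.0
  irinotecan:
    n_compartments: 3
    central_volume: 60.0
    k10: 3.5
    k12: 4.0
    k21: 2.5
    k13: 0.8
    k31: 0.25
  docetaxel:
    placeholder: true
    n_compartments: 3
    central_volume: 8.0
    k10: 6.0
    k12: 15.0
    k21: 8.0
    k13: 3.0
    k31: 0.6
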
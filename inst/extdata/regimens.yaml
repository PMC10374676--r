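# Regimen definitions. Doses in mg per m2 body surface area; start_day is the
# offset from cycle start (day 1 of a cycle = offset 0); infusion_hours is the
# administration duration. Leucovorin is scheduled but myelotoxically inert.
regimens:
  FLOT:
    cycle_length_days: 14
    default_cycles: 4
    administrations:
      - {drug: docetaxel,    dose_mg_per_m2: 50,   start_day: 0, infusion_hours: 2}
      - {drug: oxaliplatin,  dose_mg_per_m2: 85,   start_day: 0, infusion_hours: 2}
      - {drug: leucovorin,   dose_mg_per_m2: 200,  start_day: 0, infusion_hours: 2}
      - {drug: fluorouracil, dose_mg_per_m2: 2600, start_day: 0, infusion_hours: 24}
  FLO_mFOLFOX:
    cycle_length_days: 14
    default_cycles: 4
    administrations:
      - {drug: oxaliplatin,  dose_mg_per_m2: 85,   start_day: 0, infusion_hours: 2}
      - {drug: leucovorin,   dose_mg_per_m2: 200,  start_day: 0, infusion_hours: 2}
      - {drug: fluorouracil, dose_mg_per_m2: 2600, start_day: 0, infusion_hours: 24}
  FOLFIRINOX:
    cycle_length_days: 14
    default_cycles: 8
    administrations:
      - {drug: oxaliplatin,  dose_mg_per_m2: 85,   start_day: 0, infusion_hours: 2}
      - {drug: irinotecan,   dose_mg_per_m2: 180,  start_day: 0, infusion_hours: 2}
      - {drug: leucovorin,   dose_mg_per_m2: 400,  start_day: 0, infusion_hours: 2}
      - {drug: fluorouracil, dose_mg_per_m2: 400,  start_day: 0, infusion_hours: 0.0833333333}
      - {drug: fluorouracil, dose_mg_per_m2: 2400, start_day: 0, infusion_hours: 46}
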
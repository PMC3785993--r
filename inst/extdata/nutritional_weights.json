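{
  "weight": 1,
  "body_mass_index": 1,
  "lean_mass": 1,
  "fat_mass": 1,
  "total_water": 1,
  "total_protein": 1,
  "serum_albumin": 1,
  "lymphocytes": 1,
  "hemoglobin": 1
}
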
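{
  "reference_country": "Sweden",
  "national_population": 10551707,
  "population_under18": 2176224,
  "population_18plus": 8375483,
  "regional_population": 936923,
  "global_population": 8091735000,
  "prescribers_national": 28000,
  "prescriber_domains": ["cognition_communication", "mobility_selfcare"],
  "child_factor": 0.3
}
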
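domain,n_need,ci_low,ci_high
cognition_communication,400000,310000,510000
hearing,490000,390000,610000
mobility_selfcare,490000,390000,610000
orthotics_prosthetics,79000,44000,140000
vision,50000,23000,99000
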
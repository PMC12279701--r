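domain,n_need,ci_low,ci_high
cognition_communication,115500000,108600000,122400000
hearing,158300000,150000000,166600000
mobility_selfcare,395500000,379700000,411400000
orthotics_prosthetics,115600000,108400000,122800000
vision,76500000,71600000,81400000
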
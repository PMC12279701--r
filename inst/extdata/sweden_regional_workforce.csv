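region_id,population,domain,clinical_fte,admin_fte
three_regions_combined,936923,cognition_communication,14.5,1.0
three_regions_combined,936923,hearing,82.5,22.8
three_regions_combined,936923,mobility_selfcare,186.5,64.0
three_regions_combined,936923,orthotics_prosthetics,55.7,13.0
three_regions_combined,936923,vision,26.2,4.3
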
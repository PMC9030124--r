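model,factor,descriptor,value,range_low,range_high,range_units,provenance_class
art,dilution_nf,"gases/vapors long-term, 10 ACH, 30 m3 room",3,,,,quantitative_category
cherrie96,substance_emission_powder,very fine powder,10,,,,qualitative
art,activity_emission_liquid,careful handling,0.3,,,,qualitative
art,activity_emission_liquid,large scale space spraying,10,,,,qualitative
art,activity_emission_liquid,moderate application rate,1,0.3,3,l min-1,quantitative_category
art,activity_emission_powder,careful breaking stones,0.3,,,,qualitative
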
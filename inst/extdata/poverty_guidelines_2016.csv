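region,year,base_dollars,increment_dollars
contiguous_and_DC,2016,11880,4140
alaska,2016,14840,5180
hawaii,2016,13670,4760
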
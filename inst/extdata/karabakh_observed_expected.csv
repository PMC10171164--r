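country,sex,age_group,observed,expected,expected_lo,expected_hi
Azerbaijan,male,20-24,1240,337,188,405
Artsakh,male,20-24,83,6,0,14
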
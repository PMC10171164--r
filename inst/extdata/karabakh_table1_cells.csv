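country,sex,excess,lo,hi
Armenia,female,27,-153,270
Armenia,male,2730,2358,3187
Artsakh,female,-1,-60,21
Artsakh,male,314,251,363
Azerbaijan,female,260,-233,783
Azerbaijan,male,3121,2319,4071
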
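set	unique	reads
a_specific	1046333	1735052
b_specific	911949	1872895
shared	264417	16203557
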
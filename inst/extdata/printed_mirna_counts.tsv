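set	n
rjm_specific	23
rjc_specific	2
shared	46
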
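quantity	n
up_regulated	179
down_regulated	439
deg_mirna_targets	144
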
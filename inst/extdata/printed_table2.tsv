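class	unique_RJM	total_RJM	unique_RJC	total_RJC
Total	1176366	10318386	1310750	9493118
miRNA	503	8042	210	1542
rRNAetc	335464	3969740	324232	3476557
unann	841583	6342898	986308	6015019
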
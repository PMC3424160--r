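library	total_reads	adapter3_null	insert_null	adapter5_contaminant	too_short	polyA	clean_reads
RJM	11828863	58528	2191	10811	1397442	34	10318386
RJC	10289838	64104	2469	5252	682430	40	9493118
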
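sample	total_reads	total_mapped	unique_match	perfect_match	total_unmapped
mRJM	48971186	38461269	37970456	27411616	10509917
mRJC	49358642	38759459	38127557	27638426	10599183
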
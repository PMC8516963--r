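complex	family	color
ORC	fam01	#4c72b0
ORC	fam02	#4c72b0
ORC	fam03	#4c72b0
preRC	fam04	#dd8452
preRC	fam05	#dd8452
KT	fam06	#55a868
KT	fam07	#55a868
KT	fam08	#55a868
SAC	fam09	#c44e52
SAC	fam10	#c44e52
APC	fam11	#8172b3
APC	fam12	#8172b3
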
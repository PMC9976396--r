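sample_id	label
S001_pMMR	pMMR
S002_pMMR	pMMR
S003_pMMR	pMMR
S004_pMMR	pMMR
S005_dMMR	dMMR
S006_dMMR	dMMR
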
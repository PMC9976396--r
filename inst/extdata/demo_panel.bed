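msim1	100	122	MS01_sim	synthetic
msim1	1100	1118	MS02_sim	synthetic
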
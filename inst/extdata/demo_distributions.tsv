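sample_id	locus	length	count
S001_pMMR	MS01_sim	18	1
S001_pMMR	MS01_sim	21	1
S001_pMMR	MS01_sim	22	57
S001_pMMR	MS02_sim	17	1
S001_pMMR	MS02_sim	18	56
S001_pMMR	MS02_sim	19	1
S001_pMMR	MS02_sim	21	1
S002_pMMR	MS01_sim	19	1
S002_pMMR	MS01_sim	21	3
S002_pMMR	MS01_sim	22	51
S002_pMMR	MS02_sim	12	1
S002_pMMR	MS02_sim	17	3
S002_pMMR	MS02_sim	18	55
S003_pMMR	MS01_sim	19	1
S003_pMMR	MS01_sim	20	1
S003_pMMR	MS01_sim	21	1
S003_pMMR	MS01_sim	22	61
S003_pMMR	MS02_sim	16	1
S003_pMMR	MS02_sim	18	60
S004_pMMR	MS01_sim	20	1
S004_pMMR	MS01_sim	22	66
S004_pMMR	MS01_sim	23	1
S004_pMMR	MS02_sim	14	1
S004_pMMR	MS02_sim	17	2
S004_pMMR	MS02_sim	18	50
S005_dMMR	MS01_sim	11	1
S005_dMMR	MS01_sim	15	3
S005_dMMR	MS01_sim	16	35
S005_dMMR	MS01_sim	20	1
S005_dMMR	MS01_sim	22	33
S005_dMMR	MS02_sim	12	22
S005_dMMR	MS02_sim	13	2
S005_dMMR	MS02_sim	17	2
S005_dMMR	MS02_sim	18	24
S006_dMMR	MS01_sim	15	1
S006_dMMR	MS01_sim	16	34
S006_dMMR	MS01_sim	22	35
S006_dMMR	MS02_sim	11	1
S006_dMMR	MS02_sim	12	21
S006_dMMR	MS02_sim	14	1
S006_dMMR	MS02_sim	15	1
S006_dMMR	MS02_sim	17	1
S006_dMMR	MS02_sim	18	21
S006_dMMR	MS02_sim	19	1
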
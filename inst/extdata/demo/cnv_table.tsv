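sample_id	sex	chrom	start	end	cnv_type	origin	band
ASD0018	male	chr22	18910690	21463171	duplication	de_novo	22q11.2
ASD0027	male	chr7	72688896	74173668	duplication	de_novo	7q11.23
ASD0060	male	chr2	51046035	51696622	deletion	paternal	2p16.3
ASD0144	male	chr16	14901699	16492313	duplication	maternal	16p13.11
ASD0203	female	chr15	23596697	28012138	duplication	maternal	15q11q13
ASD0214	female	chr3	176244949	178219435	deletion	de_novo	3q26
ASD0222	female	chr3	195740002	197962430	deletion	de_novo	3q29
ASD0330	male	chr15	23597027	28729564	duplication	de_novo	15q11q13
ASD0343	male	chr1	143691670	148830060	duplication	maternal	1q21.1
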
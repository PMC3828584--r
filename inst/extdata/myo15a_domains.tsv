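domain	start	end
N_terminal	1	1223
motor	1224	1899
light_chain_motifs	1909	1942
MyTH4a	2066	2174
FERMa	2687	2867
SH3	2865	2959
MyTH4b	3051	3161
FERMb	3217	3497
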
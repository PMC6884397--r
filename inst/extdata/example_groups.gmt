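itch_cytokines	synthetic example group	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008
barrier_genes	synthetic example group	g00011	g00012	g00013	g00014	g00015	g00016	g00017	g00018	g00019	g00020
axon_guidance	synthetic example group	g00101	g00102	g00103	g00104	g00105	g00106
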
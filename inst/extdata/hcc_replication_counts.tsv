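category	class	discovery	type_I	type_II	replicated
promoter	HyperDown	12	4	1	7
promoter	HypoUp	108	61	15	32
promoter	HyperUp	21	1	10	10
promoter	HypoDown	30	10	6	14
genic_enhancer	HyperDown	14	11	1	2
genic_enhancer	HypoUp	236	155	34	47
genic_enhancer	HyperUp	34	19	7	8
genic_enhancer	HypoDown	54	42	2	10
intergenic_enhancer	HyperDown	6	6	0	0
intergenic_enhancer	HypoUp	54	45	6	3
intergenic_enhancer	HyperUp	0	0	0	0
intergenic_enhancer	HypoDown	42	34	2	6
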
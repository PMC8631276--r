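quantity	count
active_erna_intergenic_dmrs	36960
active_erna_annotated_as_enhancer	2378
all_intergenic_dmrs	283631
all_intergenic_annotated_as_enhancer	6622
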
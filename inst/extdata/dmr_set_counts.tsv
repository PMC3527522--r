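set	category	count
tissue	methylated_in_epithelium	1572
tissue	methylated_in_fibroblasts	1236
cancer	hypomethylated	1473
cancer	hypermethylated	2033
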
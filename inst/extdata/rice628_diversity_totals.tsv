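statistic	value
n_accessions	628
n_loci	262
total_alleles	2953
mean_gene_diversity	0.7620
mean_pic	0.7365
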
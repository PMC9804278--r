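grouping,n_groups,pct_among_groups,pct_among_sites,pct_within_sites
HUC10,19,65.8,6.9,27.3
Combined assignment 12 MUs,12,65.7,8.0,26.3
Combined assignment 11 MUs - Salmon + Marys,11,65.6,8.4,26.0
Admixture K = 11,11,65.1,8.7,26.2
Combined assignment 11 MUs - SF Owyhee,11,65.0,8.8,26.3
Admixture K = 13,13,64.7,8.6,26.7
Combined assignment 11 MUs - North Fork,11,64.7,9.1,26.3
Current watershed-based MUs,12,61.0,12.2,26.8
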
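tcell_signaling	synthetic T-cell signaling gene set	gene_0001	gene_0002	gene_0003	gene_0004	gene_0005
bcell_metagene	synthetic B-cell metagene	gene_0010	gene_0011	gene_0012	gene_0013
ifn_response	synthetic interferon response set	gene_0020	gene_0021	gene_0022
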
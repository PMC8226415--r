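priority	ancestor_iri	recipe
1	https://onto.invalid/TOA_0000003	gene
2	https://onto.invalid/TOA_0000015	feature
3	https://onto.invalid/TOA_0000013	phenotype
4	https://onto.invalid/TOA_0000001	none
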
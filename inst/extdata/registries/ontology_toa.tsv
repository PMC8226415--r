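# ontology=toa version=2021-03-12
iri	label	parents
https://onto.invalid/TOA_0000001	assay	
https://onto.invalid/TOA_0000002	molecular profiling assay	https://onto.invalid/TOA_0000001
https://onto.invalid/TOA_0000003	immunoprecipitation assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000004	ChIP-seq assay	https://onto.invalid/TOA_0000003
https://onto.invalid/TOA_0000005	histone modification ChIP-seq assay	https://onto.invalid/TOA_0000004
https://onto.invalid/TOA_0000006	chromatin accessibility assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000007	ATAC-seq assay	https://onto.invalid/TOA_0000006
https://onto.invalid/TOA_0000008	DNase-seq assay	https://onto.invalid/TOA_0000006
https://onto.invalid/TOA_0000009	expression profiling assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000010	RNA-seq assay	https://onto.invalid/TOA_0000009
https://onto.invalid/TOA_0000011	methylation profiling assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000012	whole-genome bisulfite sequencing assay	https://onto.invalid/TOA_0000011
https://onto.invalid/TOA_0000013	genotyping assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000014	genome-wide association study assay	https://onto.invalid/TOA_0000013
https://onto.invalid/TOA_0000015	sequence feature detection assay	https://onto.invalid/TOA_0000002
https://onto.invalid/TOA_0000016	transcription factor motif scan	https://onto.invalid/TOA_0000015
https://onto.invalid/TOA_0000100	data format	
https://onto.invalid/TOA_0000101	binary track format	https://onto.invalid/TOA_0000100
https://onto.invalid/TOA_0000102	BigWig	https://onto.invalid/TOA_0000101
https://onto.invalid/TOA_0000103	BigBed	https://onto.invalid/TOA_0000101
https://onto.invalid/TOA_0000104	BCF	https://onto.invalid/TOA_0000101
https://onto.invalid/TOA_0000105	text track format	https://onto.invalid/TOA_0000100
https://onto.invalid/TOA_0000106	BED	https://onto.invalid/TOA_0000105
https://onto.invalid/TOA_0000107	bedGraph	https://onto.invalid/TOA_0000105
https://onto.invalid/TOA_0000200	biological target entity	
https://onto.invalid/TOA_0000201	gene product	https://onto.invalid/TOA_0000200
https://onto.invalid/TOA_0000202	protein	https://onto.invalid/TOA_0000201
https://onto.invalid/TOA_0000203	messenger RNA	https://onto.invalid/TOA_0000201
https://onto.invalid/TOA_0000204	macromolecular structure	https://onto.invalid/TOA_0000200
https://onto.invalid/TOA_0000205	chromatin structure	https://onto.invalid/TOA_0000204
https://onto.invalid/TOA_0000206	sequence feature	https://onto.invalid/TOA_0000200
https://onto.invalid/TOA_0000207	transcription factor binding site	https://onto.invalid/TOA_0000206
https://onto.invalid/TOA_0000208	open chromatin region	https://onto.invalid/TOA_0000206
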
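# ontology=tos version=2021-02-19
iri	label	parents
https://onto.invalid/TOS_0000001	biospecimen	
https://onto.invalid/TOS_0000002	cell line	https://onto.invalid/TOS_0000001
https://onto.invalid/TOS_0000003	H1-hESC	https://onto.invalid/TOS_0000002
https://onto.invalid/TOS_0000004	K562	https://onto.invalid/TOS_0000002
https://onto.invalid/TOS_0000005	GM12878	https://onto.invalid/TOS_0000002
https://onto.invalid/TOS_0000006	cell type	https://onto.invalid/TOS_0000001
https://onto.invalid/TOS_0000007	lymphocyte	https://onto.invalid/TOS_0000006
https://onto.invalid/TOS_0000008	B cell	https://onto.invalid/TOS_0000007
https://onto.invalid/TOS_0000009	B cell, CD19 positive	https://onto.invalid/TOS_0000008
https://onto.invalid/TOS_0000010	T cell	https://onto.invalid/TOS_0000007
https://onto.invalid/TOS_0000011	abnormal cell type	https://onto.invalid/TOS_0000001
https://onto.invalid/TOS_0000012	leukemic cell	https://onto.invalid/TOS_0000011
https://onto.invalid/TOS_0000013	carcinoma cell	https://onto.invalid/TOS_0000011
https://onto.invalid/TOS_0000014	organism part	https://onto.invalid/TOS_0000001
https://onto.invalid/TOS_0000015	brain	https://onto.invalid/TOS_0000014
https://onto.invalid/TOS_0000016	liver	https://onto.invalid/TOS_0000014
https://onto.invalid/TOS_0000017	blood	https://onto.invalid/TOS_0000014
https://onto.invalid/TOS_0000100	phenotype	
https://onto.invalid/TOS_0000101	disease	https://onto.invalid/TOS_0000100
https://onto.invalid/TOS_0000102	multiple sclerosis	https://onto.invalid/TOS_0000101
https://onto.invalid/TOS_0000103	chronic lymphocytic leukemia	https://onto.invalid/TOS_0000101
https://onto.invalid/TOS_0000104	normal phenotype	https://onto.invalid/TOS_0000100
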
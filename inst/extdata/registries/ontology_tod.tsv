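# ontology=tod version=1.2
iri	label	parents
https://onto.invalid/TOD_0000001	data use condition	
https://onto.invalid/TOD_0000002	permitted use	https://onto.invalid/TOD_0000001
https://onto.invalid/TOD_0000003	general research use	https://onto.invalid/TOD_0000002
https://onto.invalid/TOD_0000004	health or medical or biomedical research	https://onto.invalid/TOD_0000002
https://onto.invalid/TOD_0000005	no restriction	https://onto.invalid/TOD_0000002
https://onto.invalid/TOD_0000006	population origins or ancestry research	https://onto.invalid/TOD_0000002
https://onto.invalid/TOD_0000007	use limitation	https://onto.invalid/TOD_0000001
https://onto.invalid/TOD_0000008	disease specific research	https://onto.invalid/TOD_0000007
https://onto.invalid/TOD_0000009	project specific limitation	https://onto.invalid/TOD_0000007
https://onto.invalid/TOD_0000010	publication required	https://onto.invalid/TOD_0000007
https://onto.invalid/TOD_0000011	collaboration required	https://onto.invalid/TOD_0000007
https://onto.invalid/TOD_0000012	not for profit use only	https://onto.invalid/TOD_0000007
https://onto.invalid/TOD_0000013	ethics approval required	https://onto.invalid/TOD_0000007
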
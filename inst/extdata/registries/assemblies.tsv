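name	canonical	scheme	curie
GRCh37	GRCh37	grc	insdc.gca:GCF_000001405.13
hg19	GRCh37	ucsc	insdc.gca:GCF_000001405.13
GRCh38	GRCh38	grc	insdc.gca:GCF_000001405.26
hg38	GRCh38	ucsc	insdc.gca:GCF_000001405.26
GRCm38	GRCm38	grc	insdc.gca:GCF_000001635.20
mm10	GRCm38	ucsc	insdc.gca:GCF_000001635.20
GRCm39	GRCm39	grc	insdc.gca:GCF_000001635.27
mm39	GRCm39	ucsc	insdc.gca:GCF_000001635.27
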
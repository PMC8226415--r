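prefix	pattern	url_template
insdc.gca	^GC[AF]_[0-9]{9}\.[0-9]+$	https://example.org/asm/{accession}
insdc.run	^[SED]RR[0-9]{6,}$	https://example.org/run/{accession}
taxonomy	^[0-9]+$	https://example.org/taxonomy/{accession}
pubmed	^[0-9]+$	https://example.org/pubmed/{accession}
biosample	^SAM[NED][A-Z]?[0-9]+$	https://example.org/biosample/{accession}
hgnc	^[0-9]+$	https://example.org/hgnc/{accession}
ega.experiment	^EGAX[0-9]{11}$	https://example.org/ega/experiment/{accession}
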
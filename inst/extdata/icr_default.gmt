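ICR	20-gene immunologic constant of rejection module (Th1/cytotoxic activation; literature default, configurable)	IFNG	IRF1	STAT1	IL12B	TBX21	CD8A	CD8B	CXCL9	CXCL10	CCL5	GZMA	GZMB	GZMH	GNLY	PRF1	CD274	CTLA4	FOXP3	IDO1	PDCD1
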
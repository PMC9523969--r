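immune_checkpoints	30 co-stimulatory/co-inhibitory checkpoint genes (generic literature panel, configurable)	PDCD1	CD274	PDCD1LG2	CTLA4	CD276	VTCN1	LAG3	HAVCR2	TIGIT	BTLA	CD27	CD28	CD40	CD40LG	CD70	CD80	CD86	ICOS	ICOSLG	TNFRSF4	TNFRSF9	TNFRSF18	TNFSF4	TNFSF9	TNFSF18	IDO1	ADORA2A	VSIR	CD160	CD244
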
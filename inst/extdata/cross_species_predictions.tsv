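# Reported mol-miR target predictions on the human and mouse adipogenesis
# panels: the 19 genes predicted in both species, with per-pair class
# probabilities. Used as an input fixture for the cross-species consistency
# and direction-concordance operations.
species	gene_symbol	mirna_id	probability
human	AGT	miR160h	0.65
human	AGT	miR395d	0.96
human	AGT	miR482b	0.97
human	CDKN1A	miR395d	0.93
human	CDKN1A	miR160h	0.96
human	CDKN1A	miR166	0.97
human	CFD	miR160h	0.95
human	DIO2	miR166	0.96
human	DIO2	miR396a	0.99
human	EGR2	miR166	0.60
human	EGR2	miR159c	0.82
human	INSR	miR396a	0.85
human	INSR	miR482b	0.98
human	KLF2	miR2118a	0.87
human	KLF2	miR482b	0.96
human	KLF2	miR166	0.97
human	LEP	miR159c	0.95
human	LEP	miR482b	0.96
human	LEP	miR160h	0.96
human	LEP	miR166	0.98
human	LPL	miR160h	0.61
human	MAPK14	miR393a	0.92
human	MAPK14	miR396a	0.98
human	NRF1	miR160h	0.94
human	NRF1	miR396a	0.97
human	NRF1	miR482b	0.98
human	PPARA	miR393a	0.75
human	PPARA	miR160h	0.96
human	PPARA	miR166	0.96
human	RB1	miR160h	0.86
human	RXRA	miR160h	0.97
human	RXRA	miR166	0.98
human	SFRP1	miR160h	0.84
human	SFRP1	miR166	0.84
human	SFRP1	miR482b	0.97
human	SHH	miR159c	0.95
human	SHH	miR482b	0.98
human	VDR	miR160h	0.71
human	VDR	miR166	0.97
human	WNT3A	miR171b	0.87
human	WNT3A	miR166	0.92
human	WNT3A	miR482b	0.94
human	WNT3A	miR2118a	0.96
human	WNT3A	miR160h	0.98
human	WNT10B	miR166	0.62
human	WNT10B	miR167f-3p	0.88
human	WNT10B	miR395d	0.96
human	WNT10B	miR482b	0.96
human	WNT10B	miR2118a	0.96
human	WNT10B	miR160h	0.98
mouse	AGT	miR160h	0.90
mouse	AGT	miR159c	0.90
mouse	AGT	miR167f-3p	0.96
mouse	AGT	miR397a	0.68
mouse	CDKN1A	miR160h	0.96
mouse	CFD	miR160h	0.97
mouse	DIO2	miR159c	0.94
mouse	DIO2	miR156e	0.94
mouse	DIO2	miR166	0.87
mouse	EGR2	miR167f-3p	0.95
mouse	EGR2	miR159c	0.94
mouse	INSR	miR395d	0.90
mouse	KLF2	miR166	0.97
mouse	KLF2	miR160h	0.88
mouse	LEP	miR395d	0.95
mouse	LEP	miR159c	0.91
mouse	LEP	miR160h	0.92
mouse	LPL	miR167f-3p	0.65
mouse	MAPK14	miR159c	0.93
mouse	NRF1	miR167f-3p	0.85
mouse	PPARA	miR397a	0.96
mouse	PPARA	miR482b	0.94
mouse	PPARA	miR160h	0.87
mouse	RB1	miR159c	0.61
mouse	RXRA	miR160h	0.93
mouse	RXRA	miR159c	0.93
mouse	RXRA	miR398a-5p	0.61
mouse	RXRA	miR166	0.61
mouse	SFRP1	miR160h	0.92
mouse	SFRP1	miR166	0.92
mouse	SHH	miR858b	0.96
mouse	SHH	miR167f-3p	0.72
mouse	VDR	miR160h	0.91
mouse	VDR	miR398a-5p	0.91
mouse	VDR	miR166	0.63
mouse	WNT3A	miR159c	0.93
mouse	WNT3A	miR395d	0.85
mouse	WNT10B	miR858b	0.96
mouse	WNT10B	miR167f-3p	0.94
mouse	WNT10B	miR160h	0.91
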
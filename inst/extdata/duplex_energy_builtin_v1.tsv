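# mircross built-in duplex nearest-neighbour energy table
# id: builtin-v1; units: kcal/mol
# stack rows: 5' pair, 3' pair (read along the miRNA strand), stacking energy
param	init	4.1
param	loop_open	3.0
param	loop_ext	0.5
stack	AU	AU	-1.40
stack	AU	UA	-1.40
stack	AU	CG	-2.05
stack	AU	GC	-2.05
stack	AU	GU	-1.25
stack	AU	UG	-1.25
stack	UA	AU	-1.40
stack	UA	UA	-1.40
stack	UA	CG	-2.05
stack	UA	GC	-2.05
stack	UA	GU	-1.25
stack	UA	UG	-1.25
stack	CG	AU	-2.05
stack	CG	UA	-2.05
stack	CG	CG	-2.70
stack	CG	GC	-2.70
stack	CG	GU	-1.90
stack	CG	UG	-1.90
stack	GC	AU	-2.05
stack	GC	UA	-2.05
stack	GC	CG	-2.70
stack	GC	GC	-2.70
stack	GC	GU	-1.90
stack	GC	UG	-1.90
stack	GU	AU	-1.25
stack	GU	UA	-1.25
stack	GU	CG	-1.90
stack	GU	GC	-1.90
stack	GU	GU	-1.10
stack	GU	UG	-1.10
stack	UG	AU	-1.25
stack	UG	UA	-1.25
stack	UG	CG	-1.90
stack	UG	GC	-1.90
stack	UG	GU	-1.10
stack	UG	UG	-1.10
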
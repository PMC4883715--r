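# Simplified nearest-neighbor RNA folding parameters (kcal/mol).
# section	key1	key2	value
stack	AU	AU	-0.90
stack	AU	CG	-2.20
stack	AU	GC	-2.10
stack	AU	UA	-1.10
stack	AU	GU	-0.60
stack	AU	UG	-1.40
stack	CG	AU	-2.10
stack	CG	CG	-3.30
stack	CG	GC	-2.40
stack	CG	UA	-2.10
stack	CG	GU	-1.40
stack	CG	UG	-2.10
stack	GC	AU	-2.40
stack	GC	CG	-3.40
stack	GC	GC	-3.30
stack	GC	UA	-2.20
stack	GC	GU	-1.50
stack	GC	UG	-2.50
stack	UA	AU	-1.30
stack	UA	CG	-2.40
stack	UA	GC	-2.10
stack	UA	UA	-0.90
stack	UA	GU	-1.00
stack	UA	UG	-1.30
stack	GU	AU	-1.30
stack	GU	CG	-2.50
stack	GU	GC	-2.10
stack	GU	UA	-1.40
stack	GU	GU	-0.50
stack	GU	UG	1.30
stack	UG	AU	-1.00
stack	UG	CG	-1.50
stack	UG	GC	-1.40
stack	UG	UA	-0.60
stack	UG	GU	0.30
stack	UG	UG	-0.50
hairpin	3	.	5.40
hairpin	4	.	5.60
hairpin	5	.	5.70
hairpin	6	.	5.40
hairpin	7	.	6.00
hairpin	8	.	5.50
hairpin	9	.	6.40
hairpin	10	.	6.51
hairpin	11	.	6.62
hairpin	12	.	6.71
hairpin	13	.	6.80
hairpin	14	.	6.88
hairpin	15	.	6.95
hairpin	16	.	7.02
hairpin	17	.	7.09
hairpin	18	.	7.15
hairpin	19	.	7.21
hairpin	20	.	7.26
hairpin	21	.	7.32
hairpin	22	.	7.37
hairpin	23	.	7.41
hairpin	24	.	7.46
hairpin	25	.	7.50
hairpin	26	.	7.55
hairpin	27	.	7.59
hairpin	28	.	7.63
hairpin	29	.	7.66
hairpin	30	.	7.70
bulge	1	.	3.80
bulge	2	.	2.80
bulge	3	.	3.20
bulge	4	.	3.60
bulge	5	.	4.00
bulge	6	.	4.40
bulge	7	.	4.57
bulge	8	.	4.71
bulge	9	.	4.84
bulge	10	.	4.95
bulge	11	.	5.05
bulge	12	.	5.15
bulge	13	.	5.24
bulge	14	.	5.32
bulge	15	.	5.39
bulge	16	.	5.46
bulge	17	.	5.52
bulge	18	.	5.59
bulge	19	.	5.64
bulge	20	.	5.70
bulge	21	.	5.75
bulge	22	.	5.80
bulge	23	.	5.85
bulge	24	.	5.90
bulge	25	.	5.94
bulge	26	.	5.98
bulge	27	.	6.02
bulge	28	.	6.06
bulge	29	.	6.10
bulge	30	.	6.14
internal	2	.	1.70
internal	3	.	1.80
internal	4	.	2.00
internal	5	.	2.20
internal	6	.	2.50
internal	7	.	2.67
internal	8	.	2.81
internal	9	.	2.94
internal	10	.	3.05
internal	11	.	3.15
internal	12	.	3.25
internal	13	.	3.34
internal	14	.	3.42
internal	15	.	3.49
internal	16	.	3.56
internal	17	.	3.62
internal	18	.	3.69
internal	19	.	3.74
internal	20	.	3.80
internal	21	.	3.85
internal	22	.	3.90
internal	23	.	3.95
internal	24	.	4.00
internal	25	.	4.04
internal	26	.	4.08
internal	27	.	4.12
internal	28	.	4.16
internal	29	.	4.20
internal	30	.	4.24
multiloop	close	.	3.40
multiloop	branch	.	0.40
multiloop	unpaired	.	0.10
misc	lxc	.	1.08
misc	min_loop	.	3
misc	max_interior	.	30
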
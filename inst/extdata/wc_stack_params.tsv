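param	key	value
# Watson-Crick nearest-neighbor stacking free energies, dG37 kcal/mol
# (Xia et al. 1998 / Turner rules). Key "ab/cd": top strand 5'-ab-3'
# over bottom strand 3'-cd-5', pairs a:c and b:d. All 16 ordered entries
# are written out; rotationally symmetric steps share one value.
stack	AA/UU	-0.93
stack	UU/AA	-0.93
stack	AU/AU	-1.10
stack	UA/UA	-1.33
stack	CU/GA	-2.08
stack	AG/UC	-2.08
stack	CA/GU	-2.11
stack	UG/AC	-2.11
stack	GU/CA	-2.24
stack	AC/UG	-2.24
stack	GA/CU	-2.35
stack	UC/AG	-2.35
stack	CG/GC	-2.36
stack	GG/CC	-3.26
stack	CC/GG	-3.26
stack	GC/CG	-3.42
init_penalty		4.09
bulge_open		3.8
bulge_extend		0.5
internal_open		2.0
internal_extend		0.4
allow_gu		0
max_loop		15
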
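# FNT reference frame annotation (FocA / PDB 3KCU numbering).
# The reference sequence is SYNTHETIC: it satisfies every residue asserted
# for the reference frame in the study tables but is not the crystal
# structure's sequence. Substitute a real sequence via load_reference().
# Schema: 'key<TAB>value' lines, 'segment<TAB>name<TAB>start<TAB>end' rows,
# 'residue<TAB>position<TAB>aa' rows, 'site<TAB>kind<TAB>state<TAB>positions(csv)'.
name	FocA_3KCU_synthetic
offset	1
sequence	SNPDEGSNPDEGSNPDEGSNPDEGSNPDEGLLATIFLALLAGIFISLAAVIFMVLLPDEGSNPLAVIFMVLGAVFFMGLLACVFMGLDLFTSTVLLAVIKMGSNPDIFMVLLNVIFMVLGNVIGAVLLVVIFMVPDEGSNPDEGSNPDEGSNPDEGSNPDAVIFMVLGAVANMVVCAAVFMVLLEGSFMVKLAVMFMVVLAFIFMGLEHVIANVLLAVIGMVLLPDEGSNPDEGSNPDEGSNPDEGLLAVIFMNLLAVIFGNLLGGIFMVGLAVIGSNPDEGSNP
segment	TM1	31	56
segment	TM2a	64	85
segment	OMEGA	86	93
segment	TM2b	94	101
segment	TM3	107	134
segment	TM4	161	184
segment	TM5a	188	204
segment	S	205	209
segment	TM5b	210	224
segment	TM6	247	275
site	central	na	75,202,209,212
site	slit	closed	79,89,91,175
site	slit	open	79,89,90,172,175
residue	34	T
residue	37	L
residue	38	A
residue	41	A
residue	42	G
residue	45	I
residue	46	S
residue	48	A
residue	72	G
residue	75	F
residue	78	G
residue	79	L
residue	82	C
residue	83	V
residue	86	G
residue	88	D
residue	89	L
residue	90	F
residue	91	T
residue	92	S
residue	93	T
residue	100	K
residue	113	N
residue	120	G
residue	121	N
residue	124	G
residue	125	A
residue	129	V
residue	167	L
residue	168	G
residue	171	A
residue	172	N
residue	175	V
residue	176	C
residue	178	A
residue	179	V
residue	191	K
residue	195	M
residue	199	V
residue	202	F
residue	206	G
residue	208	E
residue	209	H
residue	212	A
residue	213	N
residue	220	G
residue	254	N
residue	261	G
residue	262	N
residue	265	G
residue	266	G
residue	271	G
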
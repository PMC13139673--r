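model	site	resno	aa	plddt
AF2	orthosteric	64	K	90.65
AF2	orthosteric	66	K	90.94
AF2	orthosteric	189	T	92.86
AF2	orthosteric	292	N	80.30
AF2	orthosteric	294	R	86.87
AF2	orthosteric	311	K	93.78
AF2	allosteric	88	F	90.65
AF2	allosteric	95	F	77.73
AF2	allosteric	103	F	85.82
AF2	allosteric	105	M	92.00
AF2	allosteric	293	F	83.90
AF2	allosteric	312	V	93.72
AF3	orthosteric	64	K	86.13
AF3	orthosteric	66	K	84.82
AF3	orthosteric	189	T	88.06
AF3	orthosteric	292	N	83.42
AF3	orthosteric	294	R	84.64
AF3	orthosteric	311	K	87.68
AF3	allosteric	88	F	81.18
AF3	allosteric	95	F	74.12
AF3	allosteric	103	F	82.18
AF3	allosteric	105	M	86.68
AF3	allosteric	293	F	84.25
AF3	allosteric	312	V	88.47
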
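# Toy minimal skeleton Y-chromosome haplogroup tree.
# Columns: node <TAB> parent <TAB> comma-separated SNP labels.
# Y SNPs are named markers (M168, P145, ...) handled as opaque string-matched
# tokens; the F branch carries P145/P160, the rare E1b1a1 outlier carries P293.
Y-MRCA
BT	Y-MRCA	M91
CT	BT	M168
C	CT	M216
DE	CT	M145
E	DE	M96
E1b1a1	E	P2,P293
CF	CT	P143
F	CF	M89,P145,P160
G	F	M201
H	F	M69
IJK	F	L15
IJ	IJK	P123
I	IJ	M170
I1	I	M253
J	IJ	M304
K	IJK	M9
O	K	M175
R	K	M207
R1	R	M173
R1a	R1	M420
R1b	R1	M343
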
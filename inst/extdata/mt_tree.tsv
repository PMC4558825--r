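# Toy mtDNA haplogroup reference tree (Phylotree-style variant annotation).
# Columns: node <TAB> parent <TAB> comma-separated variant tokens.
# Bare-position tokens (e.g. 1692) carry a wildcard allele; "!" marks a back
# mutation that reverts the upstream variant at that position; ranges with a
# trailing "d" are deletions (8281-8289d is the Polynesian-motif 9-bp deletion).
mt-MRCA
L3	mt-MRCA	A769G,A1018G
M	L3	T489C,C10400T
M7	M	C199T
M7c	M7	T146C
N	L3	G8701A,C9540T
R	N	T12705C,T16189C
R0	R	G73A
HV	R0	T14766C
H	HV	G2706A,T7028C
H1	H	G3010A
H3	H	T6776C
V	HV	G4580A
U	R	A11467G,G12308A
K	U	G9055A
JT	R	G11251A
J	JT	C295T
T	JT	C709T
P	R	G15607A
B4'5	R	T16217C
B4	B4'5	8281-8289d,A15746G
B5	B4'5	A8584G
B4a	B4	C16261T
B4a1	B4a	T5465C
B4a1a	B4a1	A6719G
B4a1a1	B4a1a	C12239T
B4a1a1c	B4a1a1	T16217C!
B4a1a1m	B4a1a1	151,1692,2416
B4a1a1a14	B4a1a1	151,1692,2416,6905
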
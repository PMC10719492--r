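aa	sidechain_atoms	compactness	charge	hydrophobicity
A	1	1	0	0.62
R	7	6	1	-2.53
N	4	3	0	-0.78
D	4	3	-1	-0.9
C	2	2	0	0.29
Q	5	4	0	-0.85
E	5	4	-1	-0.74
G	0	0	0	0.48
H	6	4	0.5	-0.4
I	4	3	0	1.38
L	4	3	0	1.06
K	5	5	1	-1.5
M	4	4	0	0.64
F	7	5	0	1.19
P	3	3	0	0.12
S	2	2	0	-0.18
T	3	2	0	-0.05
W	10	6	0	0.81
Y	8	6	0	0.26
V	3	2	0	1.08
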
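residue	avg_mass	background_freq	pka_side	charge_sign
A	71.0788	0.07805	NA	0
C	103.1388	0.01925	8.5	-1
D	115.0886	0.05364	3.9	-1
E	129.1155	0.06295	4.1	-1
F	147.1766	0.03856	NA	0
G	57.0519	0.07377	NA	0
H	137.1411	0.02199	6.5	1
I	113.1594	0.05142	NA	0
K	128.1741	0.05744	10.8	1
L	113.1594	0.09019	NA	0
M	131.1926	0.02243	NA	0
N	114.1038	0.04487	NA	0
P	97.1167	0.05203	NA	0
Q	128.1307	0.04264	NA	0
R	156.1875	0.05129	12.5	1
S	87.0782	0.0712	NA	0
T	101.1051	0.05841	NA	0
V	99.1326	0.06441	NA	0
W	186.2132	0.0133	NA	0
Y	163.176	0.03216	10.1	-1
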
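# Residue property table for proteins (20 units x 3 properties):
# Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, average residue
# mass (Da). Columns are z-scored across the 20 residues before use.
unit	hydrophobicity	hydrophilicity	mass
A	1.8	-0.5	71.08
C	2.5	-1.0	103.14
D	-3.5	3.0	115.09
E	-3.5	3.0	129.12
F	2.8	-2.5	147.18
G	-0.4	0.0	57.05
H	-3.2	-0.5	137.14
I	4.5	-1.8	113.16
K	-3.9	3.0	128.17
L	3.8	-1.8	113.16
M	1.9	-1.3	131.19
N	-3.5	0.2	114.10
P	-1.6	0.0	97.12
Q	-3.5	0.2	128.13
R	-4.5	3.0	156.19
S	-0.8	0.3	87.08
T	-0.7	-0.4	101.10
V	4.2	-1.5	99.13
W	-0.9	-3.4	186.21
Y	-1.3	-2.3	163.18
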
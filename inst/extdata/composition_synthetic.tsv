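aa	fraction
A	0.07
R	0.05
N	0.04
D	0.05
C	0.02
Q	0.04
E	0.06
G	0.07
H	0.03
I	0.06
L	0.09
K	0.06
M	0.02
F	0.04
P	0.04
S	0.06
T	0.06
W	0.02
Y	0.04
V	0.08
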
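residue	score
A	494.3
C	303.0
D	386.2
E	445.6
F	320.6
G	313.4
H	317.9
I	360.4
K	358.5
L	357.3
M	333.6
N	311.4
P	319.5
Q	326.1
R	347.1
S	265.4
T	333.0
V	362.8
W	306.5
Y	293.7
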
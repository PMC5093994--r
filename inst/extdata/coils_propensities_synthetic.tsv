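# SYNTHETIC coiled-coil propensity table (not a published matrix).
# Per-residue propensity for each heptad position a..g, constructed from
# coiled-coil heptad biology: hydrophobic residues (L, M, I, V) favoured at
# the core positions a and d, charged/polar residues (E, Q, K, R) at the
# solvent-exposed positions, proline strongly disfavoured everywhere.
# Paired with the default Gaussian score models in coils_params():
# windows of ideal heptads score near the coiled-coil mean (~2.4), random
# sequence near the globular mean (~0.8).
# Columns: residue a b c d e f g
A	1.8	1.4	1.4	1.8	1.4	1.4	1.4
C	0.6	0.5	0.5	0.6	0.5	0.5	0.5
D	0.4	1.1	1.1	0.4	1.1	1.1	1.1
E	0.8	2.2	2.2	0.8	2.2	2.2	2.2
F	1.5	0.4	0.4	1.5	0.4	0.4	0.4
G	0.3	0.4	0.4	0.3	0.4	0.4	0.4
H	0.6	0.8	0.8	0.6	0.8	0.8	0.8
I	3.2	0.5	0.5	3.2	0.5	0.5	0.5
K	0.7	1.9	1.9	0.7	1.9	1.9	1.9
L	4.0	0.9	0.9	4.0	0.9	0.9	0.9
M	3.0	0.9	0.9	3.0	0.9	0.9	0.9
N	0.6	1.0	1.0	0.6	1.0	1.0	1.0
P	0.05	0.05	0.05	0.05	0.05	0.05	0.05
Q	1.0	1.8	1.8	1.0	1.8	1.8	1.8
R	0.7	1.7	1.7	0.7	1.7	1.7	1.7
S	0.7	0.9	0.9	0.7	0.9	0.9	0.9
T	0.7	0.8	0.8	0.7	0.8	0.8	0.8
V	2.5	0.5	0.5	2.5	0.5	0.5	0.5
W	0.8	0.4	0.4	0.8	0.4	0.4	0.4
Y	0.9	0.6	0.6	0.9	0.6	0.6	0.6
X	1	1	1	1	1	1	1
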
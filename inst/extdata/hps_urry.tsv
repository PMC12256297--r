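# HPS force-field bead parameters, Urry-style hydropathy scale.
# One row per bead type: 20 amino acids (one-letter codes) and 4
# ribonucleotides (rA, rC, rG, rU; one bead per nucleotide, charge -1).
# Units: mass amu, charge e, sigma Angstrom, lambda dimensionless,
# volume Angstrom^3. Contact radii are derived as (3V/4pi)^(1/3).
name	mass	charge	sigma	lambda	volume
A	71.079	0	5.04	0.603	88.6
R	156.188	1	6.56	0.559	173.4
N	114.104	0	5.68	0.588	114.1
D	115.089	-1	5.58	0.294	111.1
C	103.145	0	5.48	0.647	108.5
Q	128.131	0	6.02	0.559	143.8
E	129.116	-1	5.92	0.000	138.4
G	57.052	0	4.50	0.574	60.1
H	137.141	0	6.08	0.765	153.2
I	113.159	0	6.18	0.706	166.7
L	113.159	0	6.18	0.721	166.7
K	128.174	1	6.36	0.382	168.6
M	131.199	0	6.18	0.676	162.9
F	147.177	0	6.36	0.824	189.9
P	97.117	0	5.56	0.759	112.7
S	87.078	0	5.18	0.588	89.0
T	101.105	0	5.62	0.588	116.1
W	186.214	0	6.78	1.000	227.8
Y	163.176	0	6.46	0.897	193.6
V	99.133	0	5.86	0.665	140.0
rA	329.21	-1	8.40	0.30	315.0
rC	305.18	-1	8.20	0.30	288.0
rG	345.21	-1	8.50	0.30	324.0
rU	306.17	-1	8.20	0.30	286.0
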
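# trinucleotide step-parameter table
# angles in degrees, displacements in Angstrom
# coordinates 1-based; step n context = bases (n-1, n, n+1)
trinuc	tilt	roll	twist	shift	slide	rise
AAA	-1	0.5	35.600000000000001	0	-0.20000000000000001	3.3199999999999998
AAC	-0.75	0.59999999999999998	35	0.050000000000000003	-0.40000000000000002	3.3399999999999999
AAG	-0.80000000000000004	2.5	31.649999999999999	0.050000000000000003	-0.25	3.3300000000000001
AAT	-0.5	-0.25	33.549999999999997	0	-0.44999999999999996	3.3149999999999999
ACA	0	2.7000000000000002	34.450000000000003	0	-0.099999999999999978	3.3650000000000002
ACC	-0.29999999999999999	2.1499999999999999	34.049999999999997	0.050000000000000003	-0.34999999999999998	3.3799999999999999
ACG	-0.25	3.0500000000000003	32.100000000000001	0.050000000000000003	0	3.3849999999999998
ACT	0.049999999999999989	2.6000000000000001	31.049999999999997	0	-0.44999999999999996	3.3499999999999996
AGA	-0.59999999999999998	3.2000000000000002	32.299999999999997	0.050000000000000003	-0.20000000000000001	3.355
AGC	-0.29999999999999999	2.3999999999999999	33.850000000000001	0.050000000000000003	-0.20000000000000001	3.3599999999999999
AGG	-0.25	4.0499999999999998	30.700000000000003	0.050000000000000003	-0.20000000000000001	3.3700000000000001
AGT	-0.049999999999999989	2.6000000000000001	31.049999999999997	0	-0.44999999999999996	3.3499999999999996
ATA	0	1.1499999999999999	33.75	0	-0.29999999999999999	3.3650000000000002
ATC	0.29999999999999999	0.44999999999999996	34.200000000000003	0	-0.39999999999999997	3.3399999999999999
ATG	-0.25	1.8500000000000001	33	0.050000000000000003	-0.14999999999999997	3.3399999999999999
ATT	0.5	-0.25	33.549999999999997	0	-0.44999999999999996	3.3149999999999999
CAA	-0.25	2.6000000000000001	35.049999999999997	-0.050000000000000003	0.10000000000000001	3.3449999999999998
CAC	0	2.7000000000000002	34.450000000000003	0	-0.099999999999999978	3.3650000000000002
CAG	-0.049999999999999989	4.5999999999999996	31.100000000000001	0	0.050000000000000017	3.355
CAT	0.25	1.8500000000000001	33	-0.050000000000000003	-0.14999999999999997	3.3399999999999999
CCA	0.20000000000000001	4.1500000000000004	34.100000000000001	-0.050000000000000003	0.15000000000000002	3.3849999999999998
CCC	-0.10000000000000001	3.6000000000000001	33.700000000000003	0	-0.10000000000000001	3.3999999999999999
CCG	-0.050000000000000003	4.5	31.75	0	0.25	3.4050000000000002
CCT	0.25	4.0499999999999998	30.700000000000003	-0.050000000000000003	-0.20000000000000001	3.3700000000000001
CGA	-0.29999999999999999	3.6500000000000004	33.350000000000001	0	0.25	3.3900000000000001
CGC	0	2.8500000000000001	34.899999999999999	0	0.25	3.395
CGG	0.050000000000000003	4.5	31.75	0	0.25	3.4050000000000002
CGT	0.25	3.0500000000000003	32.100000000000001	-0.050000000000000003	0	3.3849999999999998
CTA	0.29999999999999999	3.8999999999999999	31.850000000000001	-0.050000000000000003	-0.099999999999999992	3.3799999999999999
CTC	0.59999999999999998	3.2000000000000002	32.299999999999997	-0.050000000000000003	-0.20000000000000001	3.355
CTG	0.049999999999999989	4.5999999999999996	31.100000000000001	0	0.050000000000000017	3.355
CTT	0.80000000000000004	2.5	31.649999999999999	-0.050000000000000003	-0.25	3.3300000000000001
GAA	-0.80000000000000004	1.2	36.25	0	-0.15000000000000002	3.3449999999999998
GAC	-0.55000000000000004	1.2999999999999998	35.649999999999999	0.050000000000000003	-0.34999999999999998	3.3650000000000002
GAG	-0.59999999999999998	3.2000000000000002	32.299999999999997	0.050000000000000003	-0.20000000000000001	3.355
GAT	-0.29999999999999999	0.44999999999999996	34.200000000000003	0	-0.39999999999999997	3.3399999999999999
GCA	0.25	2.5	37.25	-0.050000000000000003	0.15000000000000002	3.375
GCC	-0.050000000000000003	1.95	36.850000000000001	0	-0.10000000000000001	3.3899999999999997
GCG	0	2.8500000000000001	34.899999999999999	0	0.25	3.395
GCT	0.29999999999999999	2.3999999999999999	33.850000000000001	-0.050000000000000003	-0.20000000000000001	3.3599999999999999
GGA	-0.25	2.75	35.299999999999997	0	-0.10000000000000001	3.3849999999999998
GGC	0.050000000000000003	1.95	36.850000000000001	0	-0.10000000000000001	3.3899999999999997
GGG	0.10000000000000001	3.6000000000000001	33.700000000000003	0	-0.10000000000000001	3.3999999999999999
GGT	0.29999999999999999	2.1499999999999999	34.049999999999997	-0.050000000000000003	-0.34999999999999998	3.3799999999999999
GTA	0.25	2	35.200000000000003	-0.050000000000000003	-0.25	3.3899999999999997
GTC	0.55000000000000004	1.2999999999999998	35.649999999999999	-0.050000000000000003	-0.34999999999999998	3.3650000000000002
GTG	0	2.7000000000000002	34.450000000000003	0	-0.099999999999999978	3.3650000000000002
GTT	0.75	0.59999999999999998	35	-0.050000000000000003	-0.40000000000000002	3.3399999999999999
TAA	-0.5	1.8999999999999999	35.799999999999997	0	-0.050000000000000003	3.3700000000000001
TAC	-0.25	2	35.200000000000003	0.050000000000000003	-0.25	3.3899999999999997
TAG	-0.29999999999999999	3.8999999999999999	31.850000000000001	0.050000000000000003	-0.099999999999999992	3.3799999999999999
TAT	0	1.1499999999999999	33.75	0	-0.29999999999999999	3.3650000000000002
TCA	0.55000000000000004	3.2999999999999998	35.700000000000003	-0.050000000000000003	0.15000000000000002	3.3700000000000001
TCC	0.25	2.75	35.299999999999997	0	-0.10000000000000001	3.3849999999999998
TCG	0.29999999999999999	3.6500000000000004	33.350000000000001	0	0.25	3.3900000000000001
TCT	0.59999999999999998	3.2000000000000002	32.299999999999997	-0.050000000000000003	-0.20000000000000001	3.355
TGA	-0.55000000000000004	3.2999999999999998	35.700000000000003	0.050000000000000003	0.15000000000000002	3.3700000000000001
TGC	-0.25	2.5	37.25	0.050000000000000003	0.15000000000000002	3.375
TGG	-0.20000000000000001	4.1500000000000004	34.100000000000001	0.050000000000000003	0.15000000000000002	3.3849999999999998
TGT	0	2.7000000000000002	34.450000000000003	0	-0.099999999999999978	3.3650000000000002
TTA	0.5	1.8999999999999999	35.799999999999997	0	-0.050000000000000003	3.3700000000000001
TTC	0.80000000000000004	1.2	36.25	0	-0.15000000000000002	3.3449999999999998
TTG	0.25	2.6000000000000001	35.049999999999997	0.050000000000000003	0.10000000000000001	3.3449999999999998
TTT	1	0.5	35.600000000000001	0	-0.20000000000000001	3.3199999999999998
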
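# opening profile for example60 (source: synthetic)
# position is 1-based
position	base	probability
1	G	0.00042577419462923045
2	C	0.00041695567752359245
3	T	0.00016590971014506854
4	T	0.00097010621482614644
5	C	0.00048582637176569025
6	G	0.0002697781709935638
7	T	1.0918484884411417e-05
8	G	4.0753086152642753e-05
9	T	0.0024975156292925066
10	T	0.0013801780235768986
11	A	0.0011997666791994143
12	T	0.0035499442087265007
13	T	0.0018224062593939481
14	A	0.0064495564931105641
15	G	0.00043913935474925125
16	T	3.6303266901838272e-05
17	A	1.2433754115777866e-05
18	C	2.8176124340720164e-05
19	G	0.000221914302904224
20	C	0.00082767858161979008
21	T	0.00023470370350793616
22	A	0.0003561278761244
23	C	0.00035618610905705178
24	T	0.00092382476090360386
25	A	1.048038628126938e-05
26	A	0.00080384386612567958
27	C	4.4245766640662609e-05
28	G	7.178119595112285e-05
29	G	1.8577761485946831e-05
30	T	1.0880694722806369e-05
31	G	0.00020558858856243784
32	G	0.00067525323292918116
33	C	0.00026952540261204294
34	C	2.322217503424411e-05
35	T	3.0208999621605522e-05
36	A	0.0004708668977100568
37	C	5.9121699881306493e-05
38	A	2.9184187635531746e-05
39	C	1.3735399024576159e-05
40	A	1.3318308087265842e-05
41	G	1.7784380787003628e-05
42	G	1.113405551726036e-05
43	A	6.0774662040555072e-05
44	G	0.00052383816156340035
45	G	0.00027331851069191892
46	C	4.7729848428267071e-05
47	C	1.4535931061416823e-05
48	A	1.1870490144631811e-05
49	A	0.00035170421641531069
50	C	0.00097760748251352167
51	C	1.9641419135550273e-05
52	G	1.201405818368238e-05
53	T	0.0001353180688786663
54	T	0.00059864828879140238
55	G	0.00055137024184012066
56	A	0.0035056590394104714
57	T	0.0029819012783748864
58	T	0.0046100753340498329
59	T	0.0012364491383072759
60	T	0.0044726088995861819
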
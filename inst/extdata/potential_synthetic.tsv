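aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.2799	-0.0587	-0.0094	-0.0788	-0.2977	-0.0757	-0.0076	-0.3678	0.05	-0.4684	-0.4732	0.095	-0.4883	-0.5477	-0.0111	-0.0237	0.0079	-0.5142	-0.485	-0.5331
R	-0.0587	0.3977	-0.246	-1.1798	-0.2957	-0.3899	-1.3069	-0.0789	0.1919	-0.0648	-0.134	0.4298	-0.0733	-0.4543	-0.2784	-0.215	-0.3892	-0.4587	-0.5317	-0.0587
N	-0.0094	-0.246	-0.3986	-0.3833	-0.0268	-0.4744	-0.469	-0.038	-0.2514	0.0766	0.0246	-0.2213	0.0187	-0.1383	-0.33	-0.3278	-0.3099	-0.2392	-0.1589	-0.0487
D	-0.0788	-1.1798	-0.3833	0.6003	-1e-04	-0.4476	0.512	0.0101	-1.2689	0.334	0.3528	-1.3981	0.3612	0.0557	-0.0567	-0.0824	-0.0523	-0.0562	-0.0561	0.4346
C	-0.2977	-0.2957	-0.0268	-1e-04	-2.1855	-0.1097	-0.053	-0.3623	-0.1985	-0.5601	-0.7202	0.1815	-0.4739	-0.6322	-0.2641	-0.1901	0.0179	-0.554	-0.598	-0.5952
Q	-0.0757	-0.3899	-0.4744	-0.4476	-0.1097	-0.3482	-0.476	-0.0576	-0.3272	-0.0811	0.0375	-0.2498	6e-04	-0.2443	-0.2006	-0.415	-0.2757	-0.2844	-0.1857	0.0592
E	-0.0076	-1.3069	-0.469	0.512	-0.053	-0.476	0.5498	-0.0187	-1.1146	0.5065	0.2863	-1.3222	0.4922	-0.028	-0.073	-0.1871	0.0101	0.0058	0.0746	0.4424
G	-0.3678	-0.0789	-0.038	0.0101	-0.3623	-0.0576	-0.0187	-0.2894	0.0843	-0.6401	-0.6079	-0.0118	-0.678	-0.6099	-0.1087	-0.0278	-0.0903	-0.4187	-0.4948	-0.6188
H	0.05	0.1919	-0.2514	-1.2689	-0.1985	-0.3272	-1.1146	0.0843	0.2807	-0.0479	-0.0239	0.6114	0.0173	-0.4854	-0.1874	-0.1991	-0.0597	-0.4639	-0.5188	-0.0079
I	-0.4684	-0.0648	0.0766	0.334	-0.5601	-0.0811	0.5065	-0.6401	-0.0479	-1.5795	-1.5841	0.5912	-1.5591	-1.4379	-0.0238	-0.2358	-0.1169	-1.5088	-1.4668	-1.7447
L	-0.4732	-0.134	0.0246	0.3528	-0.7202	0.0375	0.2863	-0.6079	-0.0239	-1.5841	-1.4498	0.514	-1.5747	-1.4226	-0.1315	-0.2052	-0.2251	-1.5227	-1.5433	-1.6116
K	0.095	0.4298	-0.2213	-1.3981	0.1815	-0.2498	-1.3222	-0.0118	0.6114	0.5912	0.514	0.8224	0.5381	-0.3078	0.0822	-0.0854	0.3175	-0.2434	-0.3321	0.6569
M	-0.4883	-0.0733	0.0187	0.3612	-0.4739	6e-04	0.4922	-0.678	0.0173	-1.5591	-1.5747	0.5381	-1.6365	-1.5944	-0.1516	-0.2536	-0.2187	-1.7028	-1.3916	-1.5271
F	-0.5477	-0.4543	-0.1383	0.0557	-0.6322	-0.2443	-0.028	-0.6099	-0.4854	-1.4379	-1.4226	-0.3078	-1.5944	-1.6972	-0.2984	-0.2994	-0.3236	-1.8924	-1.8877	-1.4843
P	-0.0111	-0.2784	-0.33	-0.0567	-0.2641	-0.2006	-0.073	-0.1087	-0.1874	-0.0238	-0.1315	0.0822	-0.1516	-0.2984	-0.0226	-0.2172	-0.3113	-0.4648	-0.3324	-0.0801
S	-0.0237	-0.215	-0.3278	-0.0824	-0.1901	-0.415	-0.1871	-0.0278	-0.1991	-0.2358	-0.2052	-0.0854	-0.2536	-0.2994	-0.2172	-0.2905	-0.2528	-0.1919	-0.1901	-0.0849
T	0.0079	-0.3892	-0.3099	-0.0523	0.0179	-0.2757	0.0101	-0.0903	-0.0597	-0.1169	-0.2251	0.3175	-0.2187	-0.3236	-0.3113	-0.2528	-0.0653	-0.2983	-0.3875	-0.358
W	-0.5142	-0.4587	-0.2392	-0.0562	-0.554	-0.2844	0.0058	-0.4187	-0.4639	-1.5088	-1.5227	-0.2434	-1.7028	-1.8924	-0.4648	-0.1919	-0.2983	-1.8125	-1.7704	-1.4261
Y	-0.485	-0.5317	-0.1589	-0.0561	-0.598	-0.1857	0.0746	-0.4948	-0.5188	-1.4668	-1.5433	-0.3321	-1.3916	-1.8877	-0.3324	-0.1901	-0.3875	-1.7704	-1.9519	-1.4874
V	-0.5331	-0.0587	-0.0487	0.4346	-0.5952	0.0592	0.4424	-0.6188	-0.0079	-1.7447	-1.6116	0.6569	-1.5271	-1.4843	-0.0801	-0.0849	-0.358	-1.4261	-1.4874	-1.4684
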
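gene	cds_len_aligned	snps	snp_per_site	function_class	indel_sites
atpA	1491	33	0.022133	ATP synthase	0
atpB	1467	30	0.02045	ATP synthase	0
atpE	388	14	0.036082	ATP synthase	0
atpF	541	14	0.025878	ATP synthase	0
atpH	239	7	0.029289	ATP synthase	0
atpI	729	15	0.020576	ATP synthase	0
ndhA	1061	31	0.029218	NadH oxidoreductase	0
ndhB	1530	3	0.001961	NadH oxidoreductase	0
ndhC	354	9	0.025424	NadH oxidoreductase	0
ndhD	1453	44	0.030282	NadH oxidoreductase	0
ndhE	300	6	0.02	NadH oxidoreductase	0
ndhF	2106	117	0.055556	NadH oxidoreductase	3
ndhG	514	17	0.033074	NadH oxidoreductase	0
ndhH	1153	29	0.025152	NadH oxidoreductase	0
ndhI	523	20	0.038241	NadH oxidoreductase	0
ndhJ	463	14	0.030238	NadH oxidoreductase	0
ndhK	672	18	0.026786	NadH oxidoreductase	72
petA	944	19	0.020127	cytochrome b6/f complex	0
petB	637	11	0.017268	cytochrome b6/f complex	0
petD	474	9	0.018987	cytochrome b6/f complex	21
petG	114	0	0	cytochrome b6/f complex	0
petL	95	1	0.010526	cytochrome b6/f complex	0
petN	87	3	0.034483	cytochrome b6/f complex	0
psaA	2209	44	0.019919	Photosystem I	0
psaB	2168	37	0.017066	Photosystem I	0
psaC	237	9	0.037975	Photosystem I	0
psaI	109	2	0.018349	Photosystem I	0
psaJ	134	1	0.007463	Photosystem I	0
psbA	1046	16	0.015296	Photosystem II	0
psbB	1491	36	0.024145	Photosystem II	0
psbC	1361	25	0.018369	Photosystem II	36
psbD	1045	20	0.019139	Photosystem II	0
psbE	251	1	0.003984	Photosystem II	0
psbF	119	1	0.008403	Photosystem II	0
psbH	218	4	0.018349	Photosystem II	0
psbI	107	4	0.037383	Photosystem II	0
psbJ	122	1	0.008197	Photosystem II	0
psbK	177	3	0.016949	Photosystem II	0
psbL	116	1	0.008621	Photosystem II	0
psbM	105	0	0	Photosystem II	0
psbT	105	3	0.028571	Photosystem II	0
psbZ	187	2	0.010695	Photosystem II	0
rpl2	818	4	0.00489	Ribosomal Proein	0
rpl14	364	5	0.013736	Ribosomal Proein	0
rpl16	408	13	0.031863	Ribosomal Proein	0
rpl20	371	13	0.03504	Ribosomal Proein	3
rpl22	406	17	0.041872	Ribosomal Proein	9
rpl23	282	0	0	Ribosomal Proein	0
rpl32	163	2	0.01227	Ribosomal Proein	0
rpl33	202	5	0.024752	Ribosomal Proein	0
rpl36	111	3	0.027027	Ribosomal Proein	0
rpoA	985	35	0.035533	DNA-directed RNA polymerase subunit alpha	9
rpoB	3153	60	0.019029	DNA-directed RNA polymerase subunit alpha	0
rpoC1	1994	58	0.029087	DNA-directed RNA polymerase subunit alpha	15
rpoC2	3993	132	0.033058	DNA-directed RNA polymerase subunit alpha	18
rps2	692	19	0.027457	Ribosomal Protein	0
rps3	639	24	0.037559	Ribosomal Protein	0
rps4	591	15	0.025381	Ribosomal Protein	0
rps7	466	2	0.004292	Ribosomal Protein	0
rps8	391	14	0.035806	Ribosomal Protein	0
rps11	409	8	0.01956	Ribosomal Protein	0
rps12	371	1	0.002695	Ribosomal Protein	0
rps14	298	5	0.016779	Ribosomal Protein	0
rps15	265	8	0.030189	Ribosomal Protein	0
rps16	285	9	0.031579	Ribosomal Protein	0
rps18	306	3	0.009804	Ribosomal Protein	0
rps19	264	15	0.056818	Ribosomal Protein	0
accD	1491	47	0.031522	others	51
ccsA	930	36	0.03871	others	0
cemA	668	22	0.032934	others	0
clpP1	602	7	0.011628	others	0
infA	226	8	0.035398	others	0
matK	1467	72	0.04908	others	12
pafI	499	8	0.016032	others	0
pafII	537	18	0.03352	others	0
pbf1	129	3	0.023256	others	0
rbcL	1373	55	0.040058	others	0
ycf1	5077	320	0.063029	others	93
ycf2	6886	47	0.006825	others	24
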
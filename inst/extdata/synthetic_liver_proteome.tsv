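id	0	3	6	9	12	15	18	21	24	27	30	33	36	39	42	45
ALBU_MOUSE	4.81	5.7982	6.2663	6.3538	5.1715	3.5977	2.7932	2.8255	4.1122	5.1119	6.5655	6.2108	4.7329	1.9261	2.7839	2.955
CP2E1_MOUSE	5.7974	6.7137	8.3486	7.5938	6.7991	5.2546	5.0422	4.7513	6.3601	7.7334	7.1401	7.4331	5.8603	5.2121	4.7009	5.7905
ARNTL_SYN	4.53	5.1986	5.2817	4.9799	4.5394	3.5449	3.4717	3.8743	4.9113	4.8291	5.431	5.1966	4.5971	3.9089	NA	3.6215
PER2_SYN	5.5173	6.0269	6.343	5.9424	5.8384	5.0132	5.0274	5.0562	5.9836	6.42	6.5969	6.2774	5.9947	5.0362	4.4035	5.2118
NOCT_SYN	2.65	4.9793	4.5317	4.6591	NA	2.4532	1.8093	2.9227	3.7238	4.1477	5.0007	4.0694	3.842	NA	1.2566	2.4351
DBP_SYN	6.4848	7.7248	8.2539	8.2071	6.0147	5.0598	4.4501	5.6037	6.8134	6.9101	7.8422	7.309	6.5536	5.8125	5.761	NA
Q9001_SYN	7.9898	NA	8.0469	7.9151	8.2262	7.8319	7.6996	7.6638	8.2193	7.7999	7.9543	7.8174	7.5405	8.3985	8.0827	7.9001
Q9002_SYN	7.473	7.4129	6.4872	7.5375	7.0494	7.7522	6.7057	6.6883	7.1847	8.2181	6.8038	7.8516	7.108	7.7597	9.33	6.9245
Q9003_SYN	2.9342	2.8846	2.7308	2.94	2.4982	2.6088	3.2327	3.0167	2.9841	3.2307	2.8384	3.0187	3.0624	2.525	2.7937	3.3924
Q9004_SYN	7.7309	6.2434	8.4775	8.0451	7.7681	8.4523	9.4375	NA	8.2503	9.317	7.9942	7.8223	8.3466	7.0784	9.0861	9.7488
Q9005_SYN	5.1256	4.1596	4.6353	4.7654	5.2826	5.3414	4.6069	4.9818	4.2354	4.9683	4.6674	4.951	4.04	4.2376	5.0071	5.1738
Q9006_SYN	4.0388	4.8554	4.0966	3.772	4.91	5.2727	5.4306	4.93	5.4139	4.8624	6.1479	3.2261	4.5167	4.8531	3.9622	4.6612
Q9007_SYN	7.1132	7.3212	8.0434	8.6367	8.2748	7.3704	8.3779	7.4729	5.7173	8.4451	8.2489	8.4902	8.3482	7.4465	8.7972	7.4017
Q9008_SYN	8.5815	8.4991	8.5387	8.6231	8.4947	8.7102	8.4268	8.7724	9.0622	8.7961	8.4411	8.3804	8.5156	8.5628	8.503	8.3238
Q9009_SYN	5.0051	5.8869	6.5666	6.7791	6.5996	5.0101	7.1885	5.2788	5.9183	4.8455	5.8369	7.0622	5.8518	6.5155	5.5019	5.9293
Q9010_SYN	2.4443	2.3603	NA	2.0915	2.3392	2.3108	2.5479	2.1987	1.714	2.5693	2.2806	2.602	2.5507	2.6553	2.6471	2.3553
Q9011_SYN	2.0505	3.0339	2.6501	2.1885	1.502	1.965	2.5443	NA	2.7986	3.5958	2.787	3.0614	2.3506	2.076	2.6738	3.4067
Q9012_SYN	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	9.8548	10.2945	9.3369
CONST_SYN	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234	5.1234
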
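donor	tissue1	tissue2	tissue3	tissue4	tissue5
DONOR01	-0.9	-0.9857	-0.1017	-0.6113	0.6851
DONOR02	1.6367	2.3785	2.8614	2.5618	3.7197
DONOR03	2.5764	1.7204	5.066	1.345	3.0957
DONOR04	1.9633	2.6251	4.1418	3.9859	3.3407
DONOR05	3.4878	2.2504	2.0285	2.0579	3.0057
DONOR06	-0.1309	0.2821	0.0801	0.1225	0.7463
DONOR07	2.5557	2.774	3.5952	2.777	4.6806
DONOR08	-0.7693	1.1921	1.1409	1.0782	0.0698
DONOR09	2.5742	4.5334	3.7115	2.0558	3.3176
DONOR10	-0.3373	1.0102	-0.7638	1.0397	-0.6784
DONOR11	2.258	2.31	4.2791	2.7126	3.8103
DONOR12	3.0448	1.9008	1.617	5.1174	3.7494
DONOR13	0.6224	2.4687	0.8418	1.8885	2.3699
DONOR14	-0.4962	2.2656	0.6869	-0.5035	-0.3727
DONOR15	-0.7313	-0.0754	-0.0419	0.7771	-0.9241
DONOR16	3.2791	3.9699	1.5124	2.1685	2.8817
DONOR17	1.805	0.2256	2.6202	1.8662	1.6608
DONOR18	0.0576	-0.5061	-0.2817	0.2342	-1.4862
DONOR19	2.368	2.4808	2.7377	4.5429	1.9421
DONOR20	-0.0099	0.6972	0.3265	0.612	1.4811
DONOR21	2.2518	1.7652	2.9723	0.647	2.2783
DONOR22	1.1915	-0.1713	-1.6711	-0.4434	2.3944
DONOR23	1.4921	2.8927	0.4724	2.7945	1.7524
DONOR24	2.3726	4.6683	2.9022	3.8976	1.4797
DONOR25	2.4448	3.4998	4.0869	2.7272	2.7637
DONOR26	4.3904	3.3957	0.717	1.555	0.5744
DONOR27	4.3273	3.5696	3.6041	1.0309	1.9855
DONOR28	-0.2255	-0.7236	0.5411	0.3953	-0.0352
DONOR29	1.7858	4.6973	3.8451	1.9371	0.257
DONOR30	3.1334	2.0052	2.3045	1.7407	1.1042
DONOR31	1.1254	1.6614	3.8379	1.6784	2.4883
DONOR32	1.5113	4.3279	2.822	1.3178	1.805
DONOR33	1.9507	2.6299	0.5672	3.026	2.0207
DONOR34	0.0496	-0.7584	-0.543	-0.1783	0.9007
DONOR35	2.6904	2.8196	2.6774	2.943	1.7702
DONOR36	3.2659	3.0896	3.298	2.6583	2.935
DONOR37	2.1709	4.5504	3.0493	2.8615	4.0406
DONOR38	2.3051	2.3663	1.9072	4.0642	1.5082
DONOR39	1.2279	2.2569	2.7905	1.2779	2.5865
DONOR40	3.7418	2.9504	2.0186	2.5602	1.2562
DONOR41	-0.9144	-0.0655	0.6464	1.3279	1.8126
DONOR42	2.2004	2.5733	2.3391	1.5729	2.5824
DONOR43	3.1705	3.9848	2.8959	3.3633	2.2824
DONOR44	0.5535	1.1785	0.5514	2.2487	1.8074
DONOR45	2.7523	1.6392	1.0223	1.6176	1.6738
DONOR46	2.6695	3.0036	1.2254	2.2082	3.8312
DONOR47	-0.9184	-1.1123	-0.4644	-0.6009	1.0983
DONOR48	3.7147	1.5849	2.8393	2.8466	1.9866
DONOR49	0.2367	-0.5809	-0.0118	-0.5431	0.0389
DONOR50	3.4932	1.1067	3.5239	2.4222	2.3843
DONOR51	0.0358	0.9059	1.4896	-1.435	0.3786
DONOR52	0.793	3.3174	2.5017	2.1977	3.1917
DONOR53	3.573	3.965	2.575	1.5811	3.087
DONOR54	1.0221	-0.433	-0.3169	-0.7451	-0.5266
DONOR55	2.1813	2.9405	2.105	3.0631	3.2012
DONOR56	0.8903	3.2495	3.2787	3.1438	1.9754
DONOR57	0.0114	0.387	0.6334	0.8538	1.2116
DONOR58	-0.953	0.0542	1.0209	1.952	0.0597
DONOR59	2.1541	2.9361	2.9301	0.8892	2.0553
DONOR60	0.8023	0.1787	3.3549	2.7934	2.7248
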
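##fileformat=VCFv4.2
##contig=<ID=1>
##contig=<ID=X>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	DONOR01	DONOR02	DONOR03	DONOR04	DONOR05	DONOR06	DONOR07	DONOR08	DONOR09	DONOR10	DONOR11	DONOR12	DONOR13	DONOR14	DONOR15	DONOR16	DONOR17	DONOR18	DONOR19	DONOR20	DONOR21	DONOR22	DONOR23	DONOR24	DONOR25	DONOR26	DONOR27	DONOR28	DONOR29	DONOR30	DONOR31	DONOR32	DONOR33	DONOR34	DONOR35	DONOR36	DONOR37	DONOR38	DONOR39	DONOR40	DONOR41	DONOR42	DONOR43	DONOR44	DONOR45	DONOR46	DONOR47	DONOR48	DONOR49	DONOR50	DONOR51	DONOR52	DONOR53	DONOR54	DONOR55	DONOR56	DONOR57	DONOR58	DONOR59	DONOR60
1	995500	rs00001	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	1/1	0/1	0/1	0/0	0/0	1/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/1	1/1	0/0	0/1	1/1	0/1	0/1	0/1	0/0	1/1	0/1	0/1	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/1	1/1	0/0	1/1	0/0	1/1	0/0	1/1	1/1	0/0	1/1	0/1	0/0	0/0	0/1	1/1
1	996000	rs00002	A	G	.	PASS	.	GT	0/1	0/1	1/1	0/1	0/1	0/0	1/1	0/0	0/1	0/1	1/1	0/1	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	1/1	0/0	0/1	1/1	0/1	0/1	0/1	0/0	1/1	1/1	0/1	1/1	0/0	0/1	1/1	1/1	1/1	0/0	0/0	0/1	0/1	1/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/1
1	996500	rs00003	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/1	1/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	1/1	0/0
1	997000	rs00004	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	1/1	0/1	1/1	1/1	0/0	0/0	0/1	1/1	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/0	1/1	0/1	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/1	1/1	0/1	0/0	0/1	0/1	1/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	1/1	1/1	0/1	0/1	0/0	1/1	0/1	0/1	0/1	0/1	1/1	0/0
1	997500	rs00005	A	G	.	PASS	.	GT	0/0	0/1	0/0	1/1	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1
1	998000	rs00006	A	G	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	1/1	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/1	0/0	1/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0
1	998500	rs00007	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/0	1/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/1	1/1	0/1	0/0	0/0	0/0	0/1	1/1	0/1	1/1	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/1	1/1	1/1	0/1	0/0	0/0	0/1	0/1	1/1
1	999000	rs00008	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/0
1	999500	rs00009	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	1/1	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	1/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	1/1	0/0	1/1	0/1	1/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/1	1/1	0/1	0/0	0/1	0/1	0/1
1	1000000	rs00010	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/1	1/1	0/0	0/1	0/0	0/0	0/0	0/1	1/1	1/1	0/1	1/1	0/1	0/0	1/1	0/1	1/1	0/1	1/1	0/0	0/0	0/1	1/1	0/0	0/1	0/1	1/1	0/0	0/0	1/1	0/1	0/0	1/1	1/1	0/1	0/1	0/1	0/1	0/1	0/1	1/1	0/0	1/1	0/1	0/1	0/1	0/0	0/1	0/0	1/1	0/0	1/1	0/1	0/0	0/1	0/1
1	1000500	rs00011	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	1/1	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/1	0/1	1/1	0/1	0/1	0/0	0/1	0/0	0/0	1/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	1/1
1	1001000	rs00012	A	G	.	PASS	.	GT	0/0	0/0	0/0	1/1	0/1	0/0	0/1	1/1	0/1	0/0	0/0	1/1	0/1	0/0	1/1	0/1	0/1	0/0	1/1	0/0	1/1	0/1	0/1	0/1	0/1	1/1	0/0	0/0	0/0	0/1	1/1	0/1	0/1	0/1	0/0	0/0	0/0	1/1	0/0	0/1	0/0	1/1	0/1	0/1	0/1	0/1	0/0	1/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	1/1	1/1
1	1001500	rs00013	A	G	.	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	1/1	1/1	1/1	0/1	0/1	0/1	1/1	0/1	0/0	0/0	0/0	0/0	0/0	1/1	0/1	0/0	1/1	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	1/1	0/0	1/1	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/1
1	1002000	rs00014	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/0	1/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	1/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/0
1	1002500	rs00015	A	G	.	PASS	.	GT	1/1	1/1	0/0	0/0	0/1	0/1	0/0	0/1	1/1	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	1/1	0/1	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	1/1	1/1	0/1	0/1	0/0	1/1	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/1
1	1003000	rs00016	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/1	1/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	1/1	0/0	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/1	0/1	0/0
1	1003500	rs00017	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/0	1/1	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/1	1/1	0/0	1/1	0/0	1/1	0/0	1/1	0/0	1/1	0/1	0/1	0/1	0/1	0/1	0/1	1/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	1/1	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/1	1/1	0/0	0/1	0/0	0/1
1	1004000	rs00018	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/1	1/1	1/1	0/0	1/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	1/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	1/1	0/1	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/1	1/1	0/0	1/1	0/1	1/1	0/0	0/1	0/0	0/0	0/0	0/0
1	1004500	rs00019	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	0/0	1/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	1/1	0/1	0/0	1/1	0/1	0/0	0/1	0/0	0/1	0/1	1/1	0/0	0/1	0/1	0/0	0/1	0/1	0/1	1/1	0/0	0/1	0/0	0/0	0/0	1/1	0/1	0/0	0/0	0/0	0/1
1	1005000	rs00020	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	1/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/1	1/1	0/0	0/0	1/1	1/1	0/0	0/1	1/1	0/0	1/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	1/1	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/1
1	1003100	rs_lowmaf	C	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	1003300	rs_minority3	G	A	.	PASS	.	GT	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	1003500	rs_lowcall	T	C	.	PASS	.	GT	./.	0/0	0/1	0/0	./.	0/0	1/1	0/1	0/1	0/1	0/1	0/0	1/1	0/0	0/0	./.	0/0	0/1	0/0	./.	0/1	0/0	./.	0/0	0/1	./.	./.	0/0	0/0	0/1	1/1	1/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	./.	0/1	0/1	0/1	0/0	0/0	1/1	./.	0/0	0/1	0/1	0/1	0/0	0/1	./.	0/0	0/0	0/1
X	500000	rs_chrX	A	C	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1
1	1004000	rs_multi	A	G,T	.	PASS	.	GT	0/1	0/0	0/2	0/2	1/2	0/1	0/2	1/2	1/2	0/0	0/0	1/2	1/2	0/2	0/2	0/1	0/0	1/2	0/2	0/1	0/1	0/1	1/2	0/0	0/2	0/2	0/0	0/2	0/0	0/0	0/0	0/1	0/2	0/1	0/2	0/2	0/1	0/0	0/2	0/1	1/2	0/1	0/1	1/2	1/2	0/1	0/2	0/0	0/1	1/2	0/0	0/2	0/1	0/1	0/1	0/1	0/2	1/2	0/0	0/1
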
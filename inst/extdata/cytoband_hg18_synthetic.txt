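chr1	0	41333333	p13	gneg
chr1	41333333	82666667	p12	gpos50
chr1	82666667	124000000	p11	gneg
chr1	124000000	154812430	q11	acen
chr1	154812430	185624860	q21	gneg
chr1	185624860	216437289	q31	gpos50
chr1	216437289	247249719	q41	gneg
chr2	0	31000000	p13	gneg
chr2	31000000	62000000	p12	gpos50
chr2	62000000	93000000	p11	gneg
chr2	93000000	130487787	q11	acen
chr2	130487787	167975574	q21	gneg
chr2	167975574	205463362	q31	gpos50
chr2	205463362	242951149	q41	gneg
chr3	0	30333333	p13	gneg
chr3	30333333	60666667	p12	gpos50
chr3	60666667	91000000	p11	gneg
chr3	91000000	118125457	q11	acen
chr3	118125457	145250914	q21	gneg
chr3	145250914	172376370	q31	gpos50
chr3	172376370	199501827	q41	gneg
chr4	0	16666667	p13	gneg
chr4	16666667	33333333	p12	gpos50
chr4	33333333	50000000	p11	gneg
chr4	50000000	85318266	q11	acen
chr4	85318266	120636532	q21	gneg
chr4	120636532	155954797	q31	gpos50
chr4	155954797	191273063	q41	gneg
chr5	0	16000000	p13	gneg
chr5	16000000	32000000	p12	gpos50
chr5	32000000	48000000	p11	gneg
chr5	48000000	81214466	q11	acen
chr5	81214466	114428933	q21	gneg
chr5	114428933	147643400	q31	gpos50
chr5	147643400	180857866	q41	gneg
chr6	0	20000000	p13	gneg
chr6	20000000	40000000	p12	gpos50
chr6	40000000	60000000	p11	gneg
chr6	60000000	87724998	q11	acen
chr6	87724998	115449996	q21	gneg
chr6	115449996	143174994	q31	gpos50
chr6	143174994	170899992	q41	gneg
chr7	0	19833333	p13	gneg
chr7	19833333	39666667	p12	gpos50
chr7	39666667	59500000	p11	gneg
chr7	59500000	84330356	q11	acen
chr7	84330356	109160712	q21	gneg
chr7	109160712	133991068	q31	gpos50
chr7	133991068	158821424	q41	gneg
chr8	0	15000000	p13	gneg
chr8	15000000	30000000	p12	gpos50
chr8	30000000	45000000	p11	gneg
chr8	45000000	70318706	q11	acen
chr8	70318706	95637413	q21	gneg
chr8	95637413	120956120	q31	gpos50
chr8	120956120	146274826	q41	gneg
chr9	0	16333333	p13	gneg
chr9	16333333	32666667	p12	gpos50
chr9	32666667	49000000	p11	gneg
chr9	49000000	71818313	q11	acen
chr9	71818313	94636626	q21	gneg
chr9	94636626	117454939	q31	gpos50
chr9	117454939	140273252	q41	gneg
chr10	0	13333333	p13	gneg
chr10	13333333	26666667	p12	gpos50
chr10	26666667	40000000	p11	gneg
chr10	40000000	63843684	q11	acen
chr10	63843684	87687368	q21	gneg
chr10	87687368	111531053	q31	gpos50
chr10	111531053	135374737	q41	gneg
chr11	0	17666667	p13	gneg
chr11	17666667	35333333	p12	gpos50
chr11	35333333	53000000	p11	gneg
chr11	53000000	73363096	q11	acen
chr11	73363096	93726192	q21	gneg
chr11	93726192	114089288	q31	gpos50
chr11	114089288	134452384	q41	gneg
chr12	0	11666667	p13	gneg
chr12	11666667	23333333	p12	gpos50
chr12	23333333	35000000	p11	gneg
chr12	35000000	59337384	q11	acen
chr12	59337384	83674767	q21	gneg
chr12	83674767	108012150	q31	gpos50
chr12	108012150	132349534	q41	gneg
chr13	0	5666667	p13	gneg
chr13	5666667	11333333	p12	gpos50
chr13	11333333	17000000	p11	gneg
chr13	17000000	41285745	q11	acen
chr13	41285745	65571490	q21	gneg
chr13	65571490	89857235	q31	gpos50
chr13	89857235	114142980	q41	gneg
chr14	0	5666667	p13	gneg
chr14	5666667	11333333	p12	gpos50
chr14	11333333	17000000	p11	gneg
chr14	17000000	39342146	q11	acen
chr14	39342146	61684292	q21	gneg
chr14	61684292	84026439	q31	gpos50
chr14	84026439	106368585	q41	gneg
chr15	0	6000000	p13	gneg
chr15	6000000	12000000	p12	gpos50
chr15	12000000	18000000	p11	gneg
chr15	18000000	38584729	q11	acen
chr15	38584729	59169458	q21	gneg
chr15	59169458	79754186	q31	gpos50
chr15	79754186	100338915	q41	gneg
chr16	0	12666667	p13	gneg
chr16	12666667	25333333	p12	gpos50
chr16	25333333	38000000	p11	gneg
chr16	38000000	50706814	q11	acen
chr16	50706814	63413627	q21	gneg
chr16	63413627	76120440	q31	gpos50
chr16	76120440	88827254	q41	gneg
chr17	0	7333333	p13	gneg
chr17	7333333	14666667	p12	gpos50
chr17	14666667	22000000	p11	gneg
chr17	22000000	36193686	q11	acen
chr17	36193686	50387371	q21	gneg
chr17	50387371	64581056	q31	gpos50
chr17	64581056	78774742	q41	gneg
chr18	0	5333333	p13	gneg
chr18	5333333	10666667	p12	gpos50
chr18	10666667	16000000	p11	gneg
chr18	16000000	31029288	q11	acen
chr18	31029288	46058576	q21	gneg
chr18	46058576	61087865	q31	gpos50
chr18	61087865	76117153	q41	gneg
chr19	0	9333333	p13	gneg
chr19	9333333	18666667	p12	gpos50
chr19	18666667	28000000	p11	gneg
chr19	28000000	36952913	q11	acen
chr19	36952913	45905826	q21	gneg
chr19	45905826	54858738	q31	gpos50
chr19	54858738	63811651	q41	gneg
chr20	0	9000000	p13	gneg
chr20	9000000	18000000	p12	gpos50
chr20	18000000	27000000	p11	gneg
chr20	27000000	35858991	q11	acen
chr20	35858991	44717982	q21	gneg
chr20	44717982	53576973	q31	gpos50
chr20	53576973	62435964	q41	gneg
chr21	0	2900000	p13	gneg
chr21	2900000	6800000	p12	gpos50
chr21	6800000	10900000	p11.2	gneg
chr21	10900000	13200000	p11.1	gpos50
chr21	13200000	14300000	q11.1	gneg
chr21	14300000	16000000	q11.2	gpos50
chr21	16000000	22000000	q21.1	gneg
chr21	22000000	24000000	q21.2	gpos50
chr21	24000000	31500000	q21.3	gneg
chr21	31500000	34900000	q22.11	gpos50
chr21	34900000	35900000	q22.12	gneg
chr21	35900000	37500000	q22.13	gpos50
chr21	37500000	39700000	q22.2	gneg
chr21	39700000	46944323	q22.3	gpos50
chr22	0	4666667	p13	gneg
chr22	4666667	9333333	p12	gpos50
chr22	9333333	14000000	p11	gneg
chr22	14000000	22922858	q11	acen
chr22	22922858	31845716	q21	gneg
chr22	31845716	40768574	q31	gpos50
chr22	40768574	49691432	q41	gneg
chrX	0	20000000	p13	gneg
chrX	20000000	40000000	p12	gpos50
chrX	40000000	60000000	p11	gneg
chrX	60000000	83728438	q11	acen
chrX	83728438	107456877	q21	gneg
chrX	107456877	131185316	q31	gpos50
chrX	131185316	154913754	q41	gneg
chrY	0	4000000	p13	gneg
chrY	4000000	8000000	p12	gpos50
chrY	8000000	12000000	p11	gneg
chrY	12000000	23443238	q11	acen
chrY	23443238	34886477	q21	gneg
chrY	34886477	46329716	q31	gpos50
chrY	46329716	57772954	q41	gneg
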
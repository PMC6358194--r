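snp_id	chrom	pos	effect_allele	other_allele	or
snpS01	1	1013577	A	G	1.98
snpS02	2	1027154	C	T	1.75
snpS03	3	1040731	G	A	1.62
snpS04	4	1054308	T	C	1.54
snpS05	5	1067885	A	G	1.48
snpS06	6	1081462	C	T	1.44
snpS07	7	1095039	G	A	1.4
snpS08	8	1108616	T	C	1.37
snpS09	9	1122193	A	G	1.34
snpS10	10	1135770	C	T	1.31
snpS11	11	1149347	G	A	1.29
snpS12	12	1162924	T	C	1.27
snpS13	13	1176501	A	G	1.25
snpS14	14	1190078	C	T	1.24
snpS15	15	1203655	G	A	1.22
snpS16	16	1217232	T	C	1.21
snpS17	17	1230809	A	G	1.2
snpS18	18	1244386	C	T	1.19
snpS19	19	1257963	G	A	1.18
snpS20	20	1271540	T	C	1.17
snpS21	21	1285117	A	G	1.16
snpS22	22	1298694	C	T	1.15
snpS23	1	1312271	G	A	1.14
snpS24	2	1325848	T	C	1.13
snpS25	3	1339425	A	G	1.12
snpS26	4	1353002	C	T	1.11
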
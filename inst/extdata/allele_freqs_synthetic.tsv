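locus	allele	frequency
D13S317	8	0.10
D13S317	9	0.12
D13S317	10	0.14
D13S317	11	0.14
D13S317	12	0.14
D13S317	13	0.14
D13S317	14	0.12
D13S317	15	0.10
D7S820	7	0.10
D7S820	8	0.12
D7S820	9	0.14
D7S820	10	0.14
D7S820	11	0.14
D7S820	12	0.14
D7S820	13	0.12
D7S820	14	0.10
D2S1338	16	0.06
D2S1338	17	0.13
D2S1338	18	0.06
D2S1338	19	0.06
D2S1338	20	0.13
D2S1338	21	0.06
D2S1338	22	0.06
D2S1338	23	0.13
D2S1338	24	0.13
D2S1338	25	0.06
D2S1338	26	0.06
D2S1338	27	0.06
D21S11	27	0.05
D21S11	28	0.10
D21S11	28.2	0.05
D21S11	29	0.15
D21S11	29.2	0.05
D21S11	30	0.15
D21S11	30.2	0.05
D21S11	31	0.10
D21S11	31.2	0.05
D21S11	32	0.05
D21S11	32.2	0.10
D21S11	33.2	0.10
D16S359	8	0.10
D16S359	9	0.14
D16S359	10	0.16
D16S359	11	0.16
D16S359	12	0.16
D16S359	13	0.16
D16S359	14	0.12
D18S51	10	0.05
D18S51	11	0.05
D18S51	12	0.10
D18S51	13	0.10
D18S51	14	0.10
D18S51	15	0.05
D18S51	16	0.10
D18S51	17	0.05
D18S51	18	0.05
D18S51	19	0.10
D18S51	20	0.05
D18S51	21	0.05
D18S51	22	0.05
D18S51	23	0.05
D18S51	24	0.05
CSF1PO	8	0.10
CSF1PO	9	0.14
CSF1PO	10	0.16
CSF1PO	11	0.16
CSF1PO	12	0.16
CSF1PO	13	0.16
CSF1PO	14	0.12
FGA	18	0.08
FGA	19	0.08
FGA	20	0.08
FGA	21	0.12
FGA	22	0.12
FGA	23	0.12
FGA	24	0.08
FGA	25	0.08
FGA	26	0.08
FGA	27	0.08
FGA	28	0.08
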
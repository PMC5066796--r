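species	A1	A2	A3	A4	A5	A6	B1	B2	B3	B4	B5	B6	AP2	ANT	RAV	soloist	genome_genes	genome_mb
chickpea	6	5	1	14	10	7	12	5	23	14	8	14	14	10	2	2	28269	738
pigeonpea	5	9	1	18	10	7	16	5	39	8	7	23	16	9	2	1	48680	833
common_bean	8	8	1	19	10	8	17	4	33	9	8	24	16	10	3	1	31638	521
medicago	4	7	1	14	11	4	17	6	16	6	5	16	14	7	3	0	45888	257.6
lotus	7	4	1	18	11	7	12	4	26	7	6	19	11	3	2	2	37971	472
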
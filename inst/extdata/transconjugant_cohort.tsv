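cross	recipient	donor	pct_recipient	pct_donor	n_transferred_regions	largest_region_bp
MKD8xJucho	MKD8	Jucho	98.41	1.30	6	54500
MKD8xJucho	Jucho	MKD8	91.46	4.33	23	80500
MKD8xJucho	Jucho	MKD8	89.88	6.21	22	132500
MKD8xJucho	MKD8	Jucho	87.09	10.79	15	185000
MKD8xJucho	MKD8	Jucho	99.52	0.04	4	1000
MKD8xJucho	Jucho	MKD8	81.31	13.63	32	163500
MKD8xJucho	MKD8	Jucho	95.19	4.26	10	93500
MKD8xJucho	MKD8	Jucho	96.75	2.83	10	80000
MKD8xNishi	MKD8	Nishi	97.30	3.22	27	92500
MKD8xNishi	MKD8	Nishi	98.01	2.58	10	43000
MKD8xNishi	MKD8	Nishi	90.97	8.36	13	166500
MKD8xNishi	MKD8	Nishi	87.73	12.49	14	221000
JuchoxNishi	Jucho	Nishi	97.17	3.47	36	65000
JuchoxNishi	Jucho	Nishi	90.93	9.62	28	233500
JuchoxNishi	Jucho	Nishi	90.69	9.06	19	146000
MKD8xRabinowitchi	MKD8	Rabinowitchi	91.49	8.03	16	128000
MKD8xRabinowitchi	MKD8	Rabinowitchi	99.27	0.31	3	18500
MKD8xRabinowitchi	MKD8	Rabinowitchi	96.66	2.31	4	85000
MKD8xRabinowitchi	MKD8	Rabinowitchi	94.97	4.24	11	118000
JuchoxRabinowitchi	Jucho	Rabinowitchi	97.84	1.16	11	21000
JuchoxRabinowitchi	Jucho	Rabinowitchi	97.07	2.05	12	76500
JuchoxRabinowitchi	Jucho	Rabinowitchi	95.15	3.95	16	120500
JuchoxRabinowitchi	Jucho	Rabinowitchi	91.32	7.85	18	260500
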
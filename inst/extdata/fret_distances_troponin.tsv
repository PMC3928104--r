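subunit_d	res_d	subunit_a	res_a	state	rbar_A	hw_A	model_A	crystal_1j1e_A
cTnI	131	cTnT	240	ca_saturated	48.1	10.2	50.89	38.13
cTnI	145	cTnT	240	ca_saturated	55.6	14.3	54.17	NA
cTnI	151	cTnT	240	ca_saturated	66.9	12.8	67.34	60.52
cTnI	160	cTnT	240	ca_saturated	73.3	18.1	73.37	72.57
cTnI	167	cTnT	240	ca_saturated	78.4	19.9	79.49	76.93
cTnI	131	cTnT	276	ca_saturated	20.4	1.2	21.87	18.21
cTnI	145	cTnT	276	ca_saturated	34.3	11.2	37.36	NA
cTnI	151	cTnT	276	ca_saturated	53.6	14.3	56.09	45.24
cTnI	160	cTnT	276	ca_saturated	51.8	10.7	55.21	57.12
cTnI	167	cTnT	276	ca_saturated	61.3	20.5	65.83	66.12
cTnI	17	cTnT	276	ca_saturated	54.6	16.0	53.26	NA
cTnI	27	cTnT	276	ca_saturated	45.1	9.1	44.92	NA
cTnI	40	cTnT	276	ca_saturated	38.0	13.6	40.00	NA
cTnI	131	cTnT	288	ca_saturated	25.9	4.1	21.87	NA
cTnI	145	cTnT	288	ca_saturated	39.5	17.8	37.36	NA
cTnI	151	cTnT	288	ca_saturated	51.4	16.9	56.09	NA
cTnI	160	cTnT	288	ca_saturated	55	21.3	55.21	NA
cTnI	167	cTnT	288	ca_saturated	65.4	29.2	65.83	NA
cTnI	5	cTnT	288	ca_saturated	54.9	5.6	58.59	NA
cTnI	17	cTnT	288	ca_saturated	57.6	21.9	55.99	NA
cTnI	40	cTnT	288	ca_saturated	46.9	14.2	45.47	NA
cTnI	5	cTnC	12	ca_saturated	42.6	4.7	42.07	NA
cTnI	15	cTnC	12	ca_saturated	39.9	3.3	41.92	NA
cTnI	30	cTnC	12	ca_saturated	41.3	16.6	41.24	NA
cTnI	43	cTnC	12	ca_saturated	38.8	16.3	36.33	NA
cTnI	5	cTnC	35	ca_saturated	39.6	16.4	35.54	NA
cTnI	15	cTnC	35	ca_saturated	24.9	11	25.12	NA
cTnI	30	cTnC	35	ca_saturated	16	6.5	14.76	NA
cTnI	43	cTnC	35	ca_saturated	35.5	4.1	31.10	33.65
cTnI	5	cTnC	89	ca_saturated	34.1	15.5	39.51	NA
cTnI	15	cTnC	89	ca_saturated	41.9	16.4	39.52	NA
cTnI	30	cTnC	89	ca_saturated	45.2	16.8	41.54	NA
cTnI	43	cTnC	89	ca_saturated	33.1	15.3	29.04	21.43
cTnI	5	cTnC	93	ca_saturated	47.8	13.9	40.08	NA
cTnI	15	cTnC	93	ca_saturated	33.8	15.4	38.31	NA
cTnI	30	cTnC	93	ca_saturated	39.3	16.2	40.42	NA
cTnI	43	cTnC	93	ca_saturated	28.9	3.6	24.99	22.84
cTnI	129	cTnI	5	ca_saturated	24.62	8.165	33.85	NA
cTnI	129	cTnI	15	ca_saturated	31.0	13.8	27.75	NA
cTnI	129	cTnI	30	ca_saturated	27.9	2.5	27.33	NA
cTnI	129	cTnI	43	ca_saturated	26.2	11.6	27.10	33.22
cTnI	150	cTnI	5	ca_saturated	31.2	1.2	31.92	NA
cTnI	150	cTnI	15	ca_saturated	31.8	1.2	31.20	NA
cTnI	150	cTnI	30	ca_saturated	29.7	10.5	30.42	NA
cTnI	150	cTnI	43	ca_saturated	26.9	3.1	27.42	24.50
cTnI	131	cTnT	240	ca_free	47	11.7	48.49	NA
cTnI	145	cTnT	240	ca_free	58.1	14.4	59.29	NA
cTnI	151	cTnT	240	ca_free	63.9	18.0	60.50	NA
cTnI	160	cTnT	240	ca_free	70.7	21.8	71.09	NA
cTnI	167	cTnT	240	ca_free	76.7	35.5	72.95	NA
cTnI	131	cTnT	276	ca_free	19.1	3.6	14.36	NA
cTnI	145	cTnT	276	ca_free	28.2	10.7	32.79	NA
cTnI	151	cTnT	276	ca_free	44.7	21.9	41.60	NA
cTnI	160	cTnT	276	ca_free	54.2	20.7	52.56	NA
cTnI	167	cTnT	276	ca_free	62.3	29.2	60.43	NA
cTnI	17	cTnT	276	ca_free	50.0	15.4	48.82	NA
cTnI	27	cTnT	276	ca_free	47.4	11.0	47.39	NA
cTnI	40	cTnT	276	ca_free	39.4	19.3	45.09	NA
cTnI	131	cTnT	288	ca_free	26.1	8.8	22.90	NA
cTnI	145	cTnT	288	ca_free	39.6	18.3	40.39	NA
cTnI	151	cTnT	288	ca_free	50.1	22.2	47.70	NA
cTnI	160	cTnT	288	ca_free	57.8	22.9	58.65	NA
cTnI	167	cTnT	288	ca_free	63.2	26.3	65.03	NA
cTnI	5	cTnT	288	ca_free	56.8	7.6	57.81	NA
cTnI	17	cTnT	288	ca_free	55.6	20.1	52.30	NA
cTnI	40	cTnT	288	ca_free	47.5	13.4	47.06	NA
cTnI	5	cTnC	12	ca_free	45	7.5	42.85	NA
cTnI	15	cTnC	12	ca_free	43.4	11.6	44.38	NA
cTnI	30	cTnC	12	ca_free	42.1	16.5	42.60	NA
cTnI	43	cTnC	12	ca_free	36.3	6.9	35.65	NA
cTnI	5	cTnC	35	ca_free	33.7	2.8	33.54	NA
cTnI	15	cTnC	35	ca_free	24.5	5.9	24.77	NA
cTnI	30	cTnC	35	ca_free	19.2	7.3	18.47	NA
cTnI	43	cTnC	35	ca_free	36.2	4.4	34.07	NA
cTnI	5	cTnC	89	ca_free	36.6	16	40.73	NA
cTnI	15	cTnC	89	ca_free	34.5	2.3	38.83	NA
cTnI	30	cTnC	89	ca_free	39.3	9.9	38.19	NA
cTnI	43	cTnC	89	ca_free	37.8	16.2	37.0	NA
cTnI	5	cTnC	93	ca_free	38.7	16.3	40.43	NA
cTnI	15	cTnC	93	ca_free	34.8	14.2	37.44	NA
cTnI	30	cTnC	93	ca_free	39.8	16.5	37.08	NA
cTnI	43	cTnC	93	ca_free	39.1	14.4	37.20	NA
cTnI	129	cTnI	5	ca_free	41.2	20.4	42.11	NA
cTnI	129	cTnI	15	ca_free	32.1	2.5	36.16	NA
cTnI	129	cTnI	30	ca_free	30.4	12.1	33.76	NA
cTnI	129	cTnI	43	ca_free	35.2	14.6	40.39	NA
cTnI	150	cTnI	5	ca_free	34.9	2.0	34.76	NA
cTnI	150	cTnI	15	ca_free	32.2	5.6	31.51	NA
cTnI	150	cTnI	30	ca_free	20.5	2.5	25.77	NA
cTnI	150	cTnI	43	ca_free	29.1	10.9	27.25	NA
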
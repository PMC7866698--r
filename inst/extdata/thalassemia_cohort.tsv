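family	gene	ff	snps_mp	snps_mn	snps_pp	snps_pn	mat_hap	pat_hap	cs_mat	cs_pat	nipt_mat	nipt_pat	invasive_mat	invasive_pat
F01	HBB	11.5	70	0	54	0	M_p	P_p	100	100	c.52A>T	c.126_129delCTTT	c.52A>T	c.126_129delCTTT
F02	HBB	9.4	0	99	0	35	M_n	P_n	100	100	N	N	N	N
F03	HBB	16.0	0	45	28	13	M_n	P_n	100	100	N	N	N	N
F04	HBB	12.4	40	0	57	0	M_p	P_p	100	100	c.126_129delCTTT	c.126_129delCTTT	c.126_129delCTTT	c.126_129delCTTT
F05	HBB	10.2	0	66	53	0	M_n	P_p	100	100	N	c.126_129delCTTT	N	c.126_129delCTTT
F06	HBB	15.9	36	0	0	92	M_p	P_n	100	100	c.126_129delCTTT	N	c.126_129delCTTT	N
F07	HBB	12.8	0	110	19	0	M_n	P_p	100	100	N	c.126_129delCTTT	N	c.126_129delCTTT
F08	HBB	21.8	43	3	13	340	M_p	P_n	100	100	c.126_129delCTTT	N	c.126_129delCTTT	N
F09	HBB	15.4	12	0	0	64	M_p	P_n	100	100	c.126_129delCTTT	N	c.126_129delCTTT	N
F10	HBB	17.6	26	3	0	25	M_p	P_n	100	100	c.126_129delCTTT	N	c.126_129delCTTT	N
F11	HBB	15.5	0	28	23	47	M_n	P_n	100	100	N	N	N	N
F12	HBB	7.0	0	105	0	21	M_n	P_n	100	100	N	N	N	N
F13	HBB	10.2	0	16	116	0	M_n	P_p	100	100	N	c.126_129delCTTT	N	c.126_129delCTTT
F14	HBB	15.1	60	0	70	0	M_p	P_p	100	100	c.126_129delCTTT	c.-78A>G	c.126_129delCTTT	c.-78A>G
F15	HBB	16.0	167	8	0	25	M_p	P_n	100	100	c.316-197C>T	N	c.316-197C>T	N
F16	HBB	6.0	85	0	0	51	M_p	P_n	100	100	c.316-197C>T	N	c.316-197C>T	N
F17	HBB	22.0	96	0	11	31	M_p	P_n	100	100	c.316-197C>T	N	c.316-197C>T	N
F18	HBB	15.5	72	0	3	42	M_p	P_n	100	100	c.-78A>G	N	c.-78A>G	N
F19	HBB	16.0	8	102	0	37	M_n	P_n	100	100	N	N	N	N
F20	HBB	13.5	0	59	0	4	M_n	P_n	100	100	N	N	N	N
F21	HBB	14.7	0	67	0	66	M_n	P_n	100	100	N	N	N	N
F22	HBB	14.5	38	0	39	0	M_p	P_p	100	100	c.52A>T	c.126_129delCTTT	c.52A>T	c.126_129delCTTT
F24	HBB	11.7	0	34	0	32	M_n	P_n	100	100	N	N	N	N
F25	HBB	13.1	0	40	0	61	M_n	P_n	100	100	N	N	N	N
F26	HBB	16.3	85	0	28	0	M_p	P_p	100	100	c.126_129delCTTT	c.-78A>G	c.126_129delCTTT	c.-78A>G
F27	HBA	16.0	21	0	25	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F28	HBA	7.0	51	0	21	0	M_p	P_p	100	100	--SEA	aa_WS	--SEA	aa_WS
F29	HBA	16.6	50	0	13	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F30	HBA	14.5	0	64	0	34	M_n	P_n	100	100	N	N	N	N
F31	HBA	10.5	52	0	9	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F32	HBA	16.1	0	38	39	0	M_n	P_p	100	100	N	--SEA	N	--SEA
F33	HBA	18.4	33	0	0	62	M_p	P_n	100	100	--SEA	N	--SEA	N
F34	HBA	16.5	0	20	13	0	M_n	P_p	100	100	N	--SEA	N	--SEA
F35	HBA	14.3	47	0	0	28	M_p	P_n	100	100	--SEA	N	--SEA	N
F36	HBA	20.6	49	0	0	17	M_p	P_n	100	100	--SEA	N	--SEA	N
F37	HBA	20.6	8	0	11	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F38	HBA	15.3	0	51	0	9	M_n	P_n	100	100	N	N	N	N
F39	HBA	23.9	0	36	0	25	M_n	P_n	100	100	N	N	N	N
F40	HBA	18.3	47	0	0	7	M_p	P_n	100	100	--SEA	N	--SEA	N
F41	HBA	12.3	0	43	0	34	M_n	P_n	100	100	N	N	N	N
F42	HBA	17.3	0	33	31	0	M_n	P_p	100	100	N	--SEA	N	--SEA
F43	HBA	8.8	59	0	0	13	M_p	P_n	100	100	--SEA	N	--SEA	N
F44	HBA	26.1	31	0	42	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F45	HBA	24.4	0	80	17	0	M_n	P_p	100	100	N	--SEA	N	--SEA
F46	HBA	22.4	29	0	0	19	M_p	P_n	100	100	--SEA	N	--SEA	N
F47	HBA	15.5	35	0	0	5	M_p	P_n	100	100	--SEA	N	--SEA	N
F48	HBA	11.8	0	32	0	54	M_n	P_n	100	100	N	N	N	N
F50	HBA	16.2	49	0	4	0	M_p	P_p	100	100	--SEA	--SEA	--SEA	--SEA
F51	HBA	13.7	40	0	0	35	M_p	P_n	100	100	--SEA	N	--SEA	N
F52	HBA	10.7	0	42	27	0	M_n	P_p	100	100	N	aa_CS	N	aa_CS
F54	HBA	12.8	0	44	42	0	M_n	P_p	100	100	N	--SEA	N	--SEA
F56	HBA	18.0	0	21	0	8	M_n	P_n	100	100	N	N	N	N
F23	HBB	14.0	8	0	2	0	M_p	NC	99	98	c.316-197C>T	NC	c.316-197C>T	c.316-197C>T
F49	HBA	13.6	0	1	3	0	NC	P_p	83	100	NC	--SEA	--SEA	--SEA
F53	HBA	21.9	0	1	0	35	NC	P_n	89	100	NC	N	N	N
F55	HBA	9.0	33	0	0	1	M_p	NC	100	79	--SEA	NC	N	aa_CS
F57	HBA	21.4	37	0	0	0	M_p	NC	100	0	--SEA	NC	--SEA	N
F58	HBA	22.9	61	0	0	0	M_p	NC	100	0	--SEA	NC	--SEA	--SEA
F59	HBA	14.4	13	0	1	0	M_p	NC	100	93	--SEA	NC	--SEA	--SEA
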
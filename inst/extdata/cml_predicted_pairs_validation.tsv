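# Top 20 predicted drug combinations for chronic myeloid leukemia with
# published in-vitro validation on K562 cells (WST-8 assay, 72 h).
# z_qa/z_qb: proximity z-scores of each drug module to the CML module;
# s_ab: separation between the drug modules; c_qa/c_qb: transcriptional
# correlation vs the CML module; score: T + P + C prediction score.
# survival_*: mean percent survival (+/- sd); ca: Loewe toxic-unit score
# (synergy when < 1); ia: independent-action score (synergy when >= 1).
# Three pairs (tiludronic acid / propranolol) were excluded from validation.
rank	drug_a	drug_b	z_qa	z_qb	s_ab	c_qa	c_qb	score	survival_a	sd_a	survival_b	sd_b	survival_ab	sd_ab	ca	ia
1	Capsaicin	Mitoxantrone	-7.72	-5.56	0.03	-0.18	-0.47	3.18	50.9	1.3	51.9	2.4	12.6	2.3	0.46	13.8
2	Idarubicin	Mitoxantrone	-5.13	-5.56	0.02	-0.46	-0.47	3.15	81.1	2.3	54.8	3.2	39.5	2.4	1	4.9
3	Capsaicin	Idarubicin	-7.72	-5.13	0.03	-0.18	-0.46	3.15	50.0	2.1	65.1	4.2	21.5	2.2	0.83	11.1
4	Daunorubicin	Mitoxantrone	-4.79	-5.56	0.01	-0.48	-0.47	3.13	69.6	2.2	54.5	2.7	35.9	2.9	0.55	2.0
5	Mitoxantrone	Topotecan	-5.56	-6.23	0.02	-0.47	-0.29	3.13	61.1	4.1	59.4	1.9	40.5	3.4	0.81	-4.2
6	Capsaicin	Daunorubicin	-7.72	-4.79	0.03	-0.18	-0.48	3.13	51.2	2.2	85.0	5.2	20.7	2.3	0.73	22.8
7	Capsaicin	Topotecan	-7.72	-6.23	0.03	-0.18	-0.29	3.13	55.8	0.9	61.0	4.3	28.1	2.5	0.48	5.9
8	Fasudil	Mitoxantrone	-4.16	-5.56	0.04	-0.50	-0.47	3.10	39.5	2.3	60.0	3.0	22.7	2.3	0.69	1.0
9	Capsaicin	Fasudil	-7.72	-4.16	0.04	-0.18	-0.50	3.10	53.8	3.3	39.5	2.3	15.0	1.0	1.02	6.3
10	Daunorubicin	Idarubicin	-4.79	-5.13	0.01	-0.48	-0.46	3.10	81.7	6.0	67.8	3.2	20.5	2.9	0.37	34.9
11	Idarubicin	Topotecan	-5.13	-6.23	0.02	-0.46	-0.29	3.10	65.9	3.5	59.4	1.9	42.7	4.9	0.77	-3.6
12	Mitoxantrone	Zofenopril	-5.56	-6.70	0.02	-0.47	0.16	3.10	64.6	4.3	109.2	2.3	54.3	5.9	1.72	16.1
13	Acemetacin	Mitoxantrone	-5.12	-5.56	0.04	-0.37	-0.47	3.10	92.3	5.5	64.6	4.3	47.7	3.6	1.15	11.9
14	Capsaicin	Zofenopril	-7.72	-6.70	0.02	-0.18	0.16	3.10	54.0	1.5	84.1	3.6	29.2	5.3	0.91	16.2
15	Capsaicin	Acemetacin	-7.72	-5.12	0.03	-0.18	-0.37	3.10	54.0	1.5	52.4	3.0	19.3	2.4	0.67	9.0
16	Fludarabine	Mitoxantrone	-6.97	-5.56	0.03	-0.12	-0.47	3.10	22.2	1.0	55.4	4.0	4.3	1.2	0.33	8.0
17	Mitoxantrone	Tiludronic acid	-5.56	-5.41	0.04	-0.47	0.32	3.10	NA	NA	NA	NA	NA	NA	NA	NA
18	Capsaicin	Fludarabine	-7.72	-6.97	0.03	-0.18	-0.12	3.10	58.6	2.0	66.0	3.3	17.0	2.3	0.8	21.7
19	Capsaicin	Tiludronic acid	-7.72	-5.41	0.04	-0.18	0.32	3.10	NA	NA	NA	NA	NA	NA	NA	NA
20	Mitoxantrone	Propranolol	-5.56	-4.37	0.03	-0.47	0.46	3.09	NA	NA	NA	NA	NA	NA	NA	NA
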
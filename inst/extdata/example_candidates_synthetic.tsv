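rsid	risk_allele	odds_ratio	ci_low	ci_high	race_group	study_type	citation_count	author_count	sample_size_cases	sample_size_controls	pubmed_article_count	cumulative_model_count	source	reported_strand
rs1447295	A	1.42	1.3	1.55	caucasian	meta_analysis	120	15	4000	4200	25	5	synthetic-catalog-a	forward
rs1447295	A	1.61			mixed	research	40	8	900	950	25	5	synthetic-catalog-b	forward
rs16901979	A	1.79	1.53	2.09	caucasian	research	55	22	1200	1300	12	3	synthetic-catalog-a	forward
rs6983267	G	1.26	1.2	1.33	caucasian	meta_analysis	210	30	8000	9000	30	4	synthetic-catalog-a	forward
rs6983267	G	1.4	1.25	1.57	caucasian	meta_analysis	210	30	8000	9000	30	4	synthetic-catalog-c	forward
rs1859962	G	1.2	1.11	1.31	caucasian	research	18	12	1500	1700	9	4	synthetic-catalog-b	forward
rs4430796	A	1.38			caucasian	research	62	40	2800	2900	15	4	synthetic-catalog-a	forward
rs10993994	T	1.24			mixed	research	25	9	700	800	8	2	synthetic-catalog-b	forward
rs5945572	A	1.23			caucasian	meta_analysis	33	6	2100	2400	7	2	synthetic-catalog-c	forward
rs2735839	G	2.1	1.8	2.45	caucasian	research	90	18	1100	1200	21	0	synthetic-catalog-a	forward
rs2735839	C	1.95			caucasian	research	35	11	600	650	21	0	synthetic-catalog-b	reverse
rs138213197	T	3.1	2.2	4.4	caucasian	research	150	28	2500	2600	18	0	synthetic-catalog-a	forward
rs1016343	T	1.35			other	research	5	4	80	120	3	1	synthetic-catalog-b	forward
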
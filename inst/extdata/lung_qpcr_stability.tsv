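# Published stability metrics for 21 candidate reference genes assayed by
# qPCR in 15 matched lung tumor / non-malignant parenchyma pairs: per-gene
# dCt variance, model-based (NormFinder) stability value and geNorm M value,
# with the published per-metric ranks and cumulative (rank-sum) ranks.
# Used as input to the rank-aggregation layer; the raw Ct values behind the
# metric values were not published.
gene	cumulative_rank	dct_variance	dct_rank	normfinder_stability	normfinder_rank	genorm_m	genorm_rank
NDUFA1	11	2.011	4	0.059	2	1.141	5
RPL19	14	2.252	6	0.071	4	1.140	4
RAB5C	18	2.928	10	0.058	1	1.150	7
RPS18	20	0.011	1	0.064	3	1.461	16
TBP	24	3.846	16	0.076	7	1.097	1
RPL4	27	1.523	3	0.099	12	1.253	12
ATP5J	28	2.150	5	0.090	9	1.342	14
HMGB1	29	2.648	8	0.093	10	1.210	11
TRIM27	29	3.752	15	0.073	5	1.158	9
EIF4A2	31	3.229	12	0.106	16	1.131	3
CAPZB	33	4.362	18	0.100	13	1.105	2
PPP1CB	33	3.453	13	0.104	14	1.143	6
CUL1	34	5.164	20	0.075	6	1.156	8
ACTB	37	2.731	9	0.099	11	1.638	17
B2M	38	1.517	2	0.154	21	1.369	15
HPRT1	39	3.611	14	0.105	15	1.173	10
CSTB	41	3.026	11	0.108	17	1.259	13
CD55	44	2.460	7	0.131	18	1.811	19
HSPA1A	47	7.330	21	0.077	8	1.653	18
GAPDH	58	4.044	17	0.145	20	2.093	21
SLFN13	58	4.803	19	0.132	19	1.858	20
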
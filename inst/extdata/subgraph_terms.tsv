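# Published per-term values for the GO BP subgraph fixture: longest-path
# level in the full ontology, topological position mu (mantissa/exponent
# string), topological IC, and the Zhang IC_Z / IC_Zu comparators.
go_id	level	mu	ic_t	ic_z	ic_zu
GO:0042770	6	0.0456910e-27	65.25565	10.11006	0.71747
GO:0042772	7	0.1142274e-28	66.64195	12.30729	0.87340
GO:0030330	7	0.1142274e-28	66.64195	11.20867	0.79544
GO:0000077	7	0.0171747e-34	82.35221	10.92099	0.77502
GO:0008630	10	0.0335723e-86	201.4164	12.30729	0.87340
GO:0006978	8	0.0434930e-57	134.3825	12.30729	0.87340
GO:0006977	9	0.0419985e-79	185.0743	12.30729	0.87340
GO:0042771	11	0.1278292e-116	269.1569	12.30729	0.87340
GO:0031571	8	0.1103023e-50	117.3338	12.30729	0.87340
GO:0031572	8	0.0735349e-50	117.7393	12.30729	0.87340
GO:0031573	8	0.4293676e-36	83.73851	12.30729	0.87340
GO:0031574	8	0.2206046e-50	116.6406	12.30729	0.87340
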
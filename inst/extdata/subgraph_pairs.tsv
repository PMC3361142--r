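# The 14 parent-child edges of the GO BP subgraph fixture, with published
# pairwise similarity scores: GO-universal (s_go), Wang (s_w), Zhang
# uniform-Resnik (s_zur) and Zhang-Lin (s_zl).
parent	child	s_go	s_w	s_zur	s_zl
GO:0042770	GO:0042772	0.97920	0.940	0.71747	0.90199
GO:0042770	GO:0030330	0.97920	0.940	0.71747	0.94847
GO:0042770	GO:0008630	0.32398	0.704	0.71747	0.90199
GO:0042770	GO:0000077	0.79240	0.802	0.71747	0.96144
GO:0042772	GO:0006978	0.49591	0.882	0.87340	1.00000
GO:0030330	GO:0006978	0.49591	0.889	0.79544	0.95328
GO:0030330	GO:0006977	0.36008	0.615	0.79544	0.95328
GO:0030330	GO:0042771	0.24760	0.696	0.79544	0.95328
GO:0008630	GO:0042771	0.74832	0.931	0.87340	1.00000
GO:0000077	GO:0031571	0.70186	0.830	0.77502	0.94032
GO:0000077	GO:0031572	0.69945	0.850	0.77502	0.94032
GO:0000077	GO:0031573	0.98344	0.948	0.77502	0.94032
GO:0000077	GO:0031574	0.70603	0.870	0.77502	0.94032
GO:0031571	GO:0006977	0.63398	0.774	0.87340	1.00000
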
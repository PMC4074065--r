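rank	source	target	sign	fidelity_score	validated
1	Myom1	Myom2	activation	5.65	0
2	Hbb-bh1	Hbb-y	activation	5.19	1
3	Hbb-bh1	Hba-x	activation	4.84	1
4	Hba-a1///Hba-a2	Hbb-b2	activation	4.80	1
5	Foxa3	Nr6a1	activation	4.77	0
6	Foxa3	Foxa1	activation	4.34	1
7	Lama3	Lama4	inhibition	4.18	0
8	Sox7	Fli1	activation	4.16	0
9	Sox18	Sox7	activation	4.15	0
10	Foxa3	Foxh1	activation	4.11	0
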
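	Alaska	Austria	Egypt	Mexico	Peru	Polynesia	Utah
Alaska	0.0000	0.0543	0.0994	0.0559	0.0558	0.0659	0.0953
Austria	0.0543	0.0000	0.0921	0.0601	0.0682	0.0620	0.0960
Egypt	0.0994	0.0921	0.0000	0.0909	0.1021	0.1031	0.1382
Mexico	0.0559	0.0601	0.0909	0.0000	0.0506	0.0774	0.0886
Peru	0.0558	0.0682	0.1021	0.0506	0.0000	0.0796	0.0795
Polynesia	0.0659	0.0620	0.1031	0.0774	0.0796	0.0000	0.1042
Utah	0.0953	0.0960	0.1382	0.0886	0.0795	0.1042	0.0000
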
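	Alaska	Austria	Egypt	Mexico	Peru	Polynesia	Utah
Alaska	0.0000	0.0455	0.0530	0.0580	0.0951	0.0759	0.0984
Austria	0.0455	0.0000	0.1068	0.0606	0.0984	0.0759	0.1076
Egypt	0.0530	0.1068	0.0000	0.0731	0.1110	0.0808	0.1190
Mexico	0.0580	0.0606	0.0731	0.0000	0.0443	0.1028	0.0600
Peru	0.0951	0.0984	0.1110	0.0443	0.0000	0.1443	0.0973
Polynesia	0.0759	0.0759	0.0808	0.1028	0.1443	0.0000	0.1461
Utah	0.0984	0.1076	0.1190	0.0600	0.0973	0.1461	0.0000
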
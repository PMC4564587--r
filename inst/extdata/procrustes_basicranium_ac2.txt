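	Alaska	Austria	Egypt	Mexico	Peru	Polynesia	Utah
Alaska	0.0000	0.0870	0.1289	0.0831	0.1035	0.0799	0.0888
Austria	0.0870	0.0000	0.1337	0.0765	0.0867	0.0940	0.0869
Egypt	0.1289	0.1337	0.0000	0.0948	0.1423	0.1016	0.1039
Mexico	0.0831	0.0765	0.0948	0.0000	0.0799	0.0849	0.0722
Peru	0.1035	0.0867	0.1423	0.0799	0.0000	0.1115	0.0871
Polynesia	0.0799	0.0940	0.1016	0.0849	0.1115	0.0000	0.0715
Utah	0.0888	0.0869	0.1039	0.0722	0.0871	0.0715	0.0000
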
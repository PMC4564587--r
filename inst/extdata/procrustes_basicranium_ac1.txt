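	Alaska	Austria	Egypt	Mexico	Peru	Polynesia	Utah
Alaska	0.0000	0.1580	0.1110	0.1341	0.1127	0.1045	0.1068
Austria	0.1580	0.0000	0.1611	0.1518	0.1867	0.1735	0.1485
Egypt	0.1110	0.1611	0.0000	0.0816	0.1581	0.1066	0.1040
Mexico	0.1341	0.1518	0.0816	0.0000	0.1571	0.1102	0.0908
Peru	0.1127	0.1867	0.1581	0.1571	0.0000	0.1519	0.1592
Polynesia	0.1045	0.1735	0.1066	0.1102	0.1519	0.0000	0.1019
Utah	0.1068	0.1485	0.1040	0.0908	0.1592	0.1019	0.0000
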
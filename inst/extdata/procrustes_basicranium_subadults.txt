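	Alaska	Austria	Egypt	Mexico	Peru	Polynesia	Utah
Alaska	0.0000	0.0361	0.0779	0.0398	0.0493	0.0618	0.0694
Austria	0.0361	0.0000	0.0703	0.0444	0.0513	0.0532	0.0684
Egypt	0.0779	0.0703	0.0000	0.0745	0.0846	0.0809	0.0998
Mexico	0.0398	0.0444	0.0745	0.0000	0.0411	0.0631	0.0638
Peru	0.0493	0.0513	0.0846	0.0411	0.0000	0.0740	0.0805
Polynesia	0.0618	0.0532	0.0809	0.0631	0.0740	0.0000	0.0548
Utah	0.0694	0.0684	0.0998	0.0638	0.0805	0.0548	0.0000
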
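name	element	x	y	z
P	P	-1.8959	10.8523	-1.7422
OP1	O	-0.6486	10.9959	-0.9607
OP2	O	-3.0239	11.8283	-1.1381
O5'	O	-2.4069	9.3278	-1.6614
C5'	C	-2.6374	9.0407	-0.2823
C4'	C	-3.1257	7.5989	-0.1344
O4'	O	-2.1250	6.6764	-0.6162
C3'	C	-3.3097	7.2395	1.3560
O3'	O	-4.6805	7.3648	1.7374
C2'	C	-2.8545	5.7654	1.4463
O2'	O	-3.9298	4.9345	1.8881
C1'	C	-2.4465	5.4111	-0.0008
N9	N	-1.2758	4.5318	-0.0008
C8	C	0.0287	4.9261	-0.0007
N7	N	0.8082	3.8843	-0.0005
C5	C	0.0564	2.7582	0.0056
C6	C	0.3376	1.3814	-0.0011
N6	N	1.6447	0.9264	-0.0016
N1	N	-0.6792	0.5268	-0.0004
C2	C	-1.9285	0.9528	0.0000
N3	N	-2.2403	2.2313	0.0000
C4	C	-1.2902	3.1598	0.0002
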
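name	element	x	y	z
P	P	-1.8929	10.9143	-1.7383
OP1	O	-0.6463	11.0596	-0.9565
OP2	O	-3.0218	11.8894	-1.1332
O5'	O	-2.4020	9.3896	-1.6590
C5'	C	-2.6324	9.1012	-0.2798
C4'	C	-3.1198	7.6596	-0.1323
O4'	O	-2.1177	6.7383	-0.6146
C3'	C	-3.3030	7.2992	1.3570
O3'	O	-4.6748	7.4230	1.7385
C2'	C	-2.8458	5.8247	1.4473
O2'	O	-3.9209	4.9932	1.8883
C1'	C	-2.4380	5.4725	0.0005
N9	N	-1.2664	4.5935	0.0000
C8	C	0.0390	4.9911	0.0002
N7	N	0.8179	3.9486	0.0001
C5	C	0.0609	2.8238	-0.0002
C6	C	0.3535	1.4400	-0.0010
O6	O	1.5073	1.0459	-0.0016
N1	N	-0.6769	0.5668	0.0051
C2	C	-1.9618	1.0193	-0.0011
N2	N	-2.9885	0.1086	-0.0019
N3	N	-2.2470	2.3017	-0.0004
C4	C	-1.2790	3.2252	0.0002
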
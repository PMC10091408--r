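name	element	x	y	z
P	P	-6.6792	4.2669	3.7518
OP1	O	-6.5872	2.8166	3.4739
OP2	O	-8.1134	4.8161	3.2687
O5'	O	-5.5126	5.0405	2.9567
C5'	C	-5.7134	4.7768	1.5683
C4'	C	-4.6324	5.4870	0.7524
O4'	O	-3.3228	4.9903	1.1122
C3'	C	-4.7772	5.1575	-0.7494
O3'	O	-5.4665	6.2088	-1.4288
C2'	C	-3.3225	5.0488	-1.2554
O2'	O	-3.0696	6.0273	-2.2664
C1'	C	-2.4667	5.3286	-0.0008
N1	N	-1.2701	4.4825	-0.0010
C2	C	-1.4005	3.1453	0.0024
O2	O	-2.5103	2.6509	0.0008
N3	N	-0.3174	2.3448	-0.0029
C4	C	0.9212	2.8778	-0.0007
O4	O	1.9009	2.1541	-0.0002
C5	C	1.0713	4.2844	0.0008
C6	C	-0.0315	5.0637	0.0005
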
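name	element	x	y	z
P	P	-6.6405	4.5291	3.8508
OP1	O	-6.5880	3.0714	3.6061
OP2	O	-8.0691	5.1026	3.3797
O5'	O	-5.4701	5.2558	3.0177
C5'	C	-5.7018	4.9643	1.6396
C4'	C	-4.6189	5.6273	0.7875
O4'	O	-3.3167	5.1086	1.1369
C3'	C	-4.8027	5.2635	-0.7022
O3'	O	-5.4843	6.3124	-1.3932
C2'	C	-3.3581	5.1116	-1.2333
O2'	O	-3.1052	6.0596	-2.2720
C1'	C	-2.4747	5.3992	0.0002
N1	N	-1.2987	4.5256	-0.0005
C2	C	-1.4578	3.1910	0.0003
O2	O	-2.5833	2.7201	0.0014
N3	N	-0.4065	2.3725	0.0001
C4	C	0.8281	2.8573	-0.0004
N4	N	1.9064	2.0038	-0.0002
C5	C	1.0286	4.2529	0.0037
C6	C	-0.0501	5.0707	-0.0027
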
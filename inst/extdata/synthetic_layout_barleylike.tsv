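chrom	zone	start	end	arm
1H	Z1	1	23400000	S
1H	Z2	23400001	195000000	S
1H	Z3	195000001	325000000	C
1H	Z2	325000001	496600000	L
1H	Z1	496600001	520000000	L
2H	Z1	1	30150000	S
2H	Z2	30150001	251250000	S
2H	Z3	251250001	418750000	C
2H	Z2	418750001	639850000	L
2H	Z1	639850001	670000000	L
3H	Z1	1	27900000	S
3H	Z2	27900001	232500000	S
3H	Z3	232500001	387500000	C
3H	Z2	387500001	592100000	L
3H	Z1	592100001	620000000	L
4H	Z1	1	27450000	S
4H	Z2	27450001	228750000	S
4H	Z3	228750001	381250000	C
4H	Z2	381250001	582550000	L
4H	Z1	582550001	610000000	L
5H	Z1	1	26550000	S
5H	Z2	26550001	221250000	S
5H	Z3	221250001	368750000	C
5H	Z2	368750001	563450000	L
5H	Z1	563450001	590000000	L
6H	Z1	1	26100000	S
6H	Z2	26100001	217500000	S
6H	Z3	217500001	362500000	C
6H	Z2	362500001	553900000	L
6H	Z1	553900001	580000000	L
7H	Z1	1	29700000	S
7H	Z2	29700001	247500000	S
7H	Z3	247500001	412500000	C
7H	Z2	412500001	630300000	L
7H	Z1	630300001	660000000	L
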
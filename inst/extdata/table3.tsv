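aa	resid	tautomer	state	energy
Y	576	HNd1	i	-0.45
Y	576	HNd1	o	-0.47
Y	576	HNd1-HNe2	o	-0.31
S	577	HNd1	i	-2.7
S	577	HNd1	o	-2.28
S	577	HNd1	c	-1.20
S	577	HNe2	i	-2.26
S	577	HNe2	o	-2.73
S	577	HNe2	c	-1.45
S	577	HNd1-HNe2	i	-3.31
S	577	HNd1-HNe2	o	-1.51
S	577	HNd1-HNe2	c	-1.37
L	578	HNd1	i	-0.62
L	578	HNe2	i	-0.34
L	578	HNd1-HNe2	i	-0.90
D	339	HNd1-HNe2	i	-0.86
D	339	HNd1-HNe2	o	-1.37
D	339	HNd1-HNe2	c	-1.46
Q	443	HNd1	i	-0.54
Q	443	HNd1	o	-1.18
Q	443	HNd1	c	-1.95
Q	443	HNe2	i	-0.81
Q	443	HNe2	o	-1.52
Q	443	HNe2	c	-1.56
Q	443	HNd1-HNe2	i	-0.99
Q	443	HNd1-HNe2	o	-2.65
Q	443	HNd1-HNe2	c	-1.55
D	446	HNd1-HNe2	i	-0.57
D	446	HNd1-HNe2	o	-0.83
D	446	HNd1-HNe2	c	-1.24
I	447	HNd1	o	-0.64
I	447	HNd1	c	-1.64
I	447	HNe2	o	-0.59
I	447	HNe2	c	0.71
I	447	HNd1-HNe2	o	-0.58
I	447	HNd1-HNe2	c	-1.16
R	4562	HNd1	o	-0.47
R	4562	HNd1-HNe2	c	0.35
K	2554	HNd1-HNe2	c	0.45
K	b295	HNd1-HNe2	i	0.40
K	b295	HNd1-HNe2	o	0.48
D	b299	HNd1-HNe2	i	-0.45
D	b299	HNd1-HNe2	o	-0.44
F	b300	HNd1	o	-0.88
F	b300	HNe2	i	-1.25
F	b300	HNe2	o	-0.61
F	b300	HNd1-HNe2	i	-0.91
F	b300	HNd1-HNe2	o	-1.23
Q	b438	HNd1	c	-1.13
Q	b438	HNe2	c	-1.61
Q	b438	HNd1-HNe2	c	-1.55
E	b440	HNd1	i	-0.72
E	b440	HNd1	o	-1.90
E	b440	HNd1	c	-3.48
E	b440	HNe2	i	-0.88
E	b440	HNe2	o	-2.23
E	b440	HNe2	c	-3.05
E	b440	HNd1-HNe2	i	-3.94
E	b440	HNd1-HNe2	o	-6.70
E	b440	HNd1-HNe2	c	-7.74
D	b441	HNd1-HNe2	o	-0.33
D	b441	HNd1-HNe2	c	-0.73
E	b444	HNd1-HNe2	i	-0.54
E	b444	HNd1-HNe2	c	-0.44
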
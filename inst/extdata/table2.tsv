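aa	resid	cysteines	model	state	energy	parenthesized
S	577	reduced	Ia	i	-0.86	FALSE
S	577	reduced	Ia	o	-0.58	FALSE
S	577	reduced	Ia	c	-0.80	FALSE
S	577	disulfide	Ia	i	-0.27	FALSE
S	577	disulfide	Ia	o	-0.84	FALSE
S	577	disulfide	Ia	c	-0.70	FALSE
L	578	reduced	II	o	-0.47	FALSE
L	578	disulfide	Ia	i	-0.13	FALSE
L	578	disulfide	II	o	-0.34	FALSE
L	578	disulfide	II	c	-0.45	FALSE
D	439	reduced	Ia	i	-6.5	TRUE
D	439	reduced	Ia	o	-6.7	TRUE
D	439	reduced	Ia	c	-3.4	TRUE
Q	443	reduced	Ia	i	-0.26	FALSE
Q	443	reduced	Ia	o	-0.38	FALSE
Q	443	reduced	Ia	c	-0.62	FALSE
Q	443	reduced	II	o	-0.37	FALSE
Q	443	disulfide	Ia	i	-0.41	FALSE
Q	443	disulfide	Ia	o	-0.87	FALSE
Q	443	disulfide	Ia	c	-0.27	FALSE
Q	443	disulfide	II	o	-0.28	FALSE
Q	443	disulfide	II	c	-0.30	FALSE
Q	443	reduced	Ia	i	-1.5	TRUE
Q	443	reduced	Ia	o	-1.7	TRUE
Q	443	reduced	Ia	c	-2.6	TRUE
Q	443	reduced	II	i	-2.0	TRUE
Q	443	reduced	II	c	-3.6	TRUE
D	446	reduced	Ia	c	-0.35	FALSE
D	446	reduced	Ia	i	-6.1	TRUE
D	446	reduced	II	o	-6.2	TRUE
D	446	reduced	II	c	-5.1	TRUE
I	447	reduced	Ia	o	-0.27	FALSE
I	447	reduced	Ia	c	-0.61	FALSE
I	447	disulfide	Ia	o	-0.41	FALSE
I	447	reduced	Ia	i	-1.4	TRUE
I	447	reduced	Ia	c	-0.7	TRUE
I	447	reduced	II	o	-0.6	TRUE
I	447	reduced	II	c	-1.2	TRUE
F	b300	reduced	Ia	i	-0.36	FALSE
F	b300	reduced	Ia	o	-0.26	FALSE
F	b300	disulfide	Ia	i	-0.98	FALSE
F	b300	disulfide	Ia	o	-0.42	FALSE
F	b300	reduced	Ia	i	-1.1	TRUE
E	b440	reduced	Ia	i	-0.50	FALSE
E	b440	reduced	Ia	o	-1.06	FALSE
E	b440	reduced	Ia	c	-2.21	FALSE
E	b440	disulfide	Ia	i	-1.67	FALSE
E	b440	disulfide	Ia	o	-1.20	FALSE
E	b440	disulfide	Ia	c	-1.98	FALSE
E	b440	reduced	Ia	i	-4.2	TRUE
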
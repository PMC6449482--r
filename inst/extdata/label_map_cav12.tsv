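repeat	segment	index_origin	index_max	anchor_resid	provisional	note
1	k	1	11	251	FALSE	anchored: 1k7=V257, 1k10=S260, 1k11=I261
1	o	1	25	271	FALSE	anchored: 1o2=A272, 1o6=L276
1	p	38	48	358	TRUE	no direct anchor; placed between S5 and S6 of repeat I
1	i	1	36	379	FALSE	anchored: 1i24=G402, 1i28=R406
2	k	1	11	615	TRUE	no direct anchor
2	o	1	25	635	TRUE	no direct anchor
2	p	38	48	700	TRUE	no direct anchor
2	i	1	36	727	FALSE	anchored: 2i20=N746
3	k	1	11	975	TRUE	no direct anchor
3	o	1	25	995	TRUE	no direct anchor
3	p	38	48	1070	TRUE	no direct anchor
3	i	1	36	1100	TRUE	no direct anchor
4	k	1	11	1391	FALSE	anchored: 4k7=L1397, 4k11=F1401
4	o	1	25	1411	TRUE	no direct anchor
4	p	38	48	1480	TRUE	no direct anchor
4	i	1	36	1510	TRUE	no direct anchor
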
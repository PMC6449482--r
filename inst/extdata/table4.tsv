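aa	resid	label	mutant	state	energy
I	261	1k11	G406R	open	-2.27
S	260	1k10	G406R	open	-1.38
A	262	1o2	G402S	open	-1.05
A	262	1o2	G406R	open	-0.63
N	746	2i20	G406R	open	-0.56
V	257	1k7	G406R	open	-0.38
L	269	1o6	G402S	open	-0.82
P	267	1o5	G402S	open	-0.85
P	267	1o5	G406R	closed	-0.56
K	261	1o1	G406R	closed	0.35
K	261	1o1	G406R	open	0.33
A	262	1o2	G406R	closed	-0.30
L	1397	4k7	G406R	closed	-0.30
F	1401	4k11	G402S	closed	-0.75
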
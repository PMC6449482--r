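mutant	state	energy
G402S	closed	-0.75
G402S	open	-2.72
G406R	closed	-0.81
G406R	open	-4.98
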
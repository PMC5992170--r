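aa5	aa35	base
T	N	A
T	D	G
N	D	T
N	S	C
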
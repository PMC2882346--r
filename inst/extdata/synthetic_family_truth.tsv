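# planted diagnostic sites of synthetic_family.fasta (generator seed 17)
position	residue_a	residue_b	mode
4	K	D	both
8	D	R	both
21	D	R	both
28	D	R	both
31	K	D	both
34	D	K	both
45	K	D	both
49	R	D	both
55	D	K	both
66	R	D	both
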
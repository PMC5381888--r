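chrA	0	20000	frag_1
chrA	20000	40000	frag_2
chrA	40000	70000	frag_3
chrA	70000	100000	frag_4
chrB	0	30000	frag_5
chrB	30000	60000	frag_6
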
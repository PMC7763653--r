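sample	18-3	4-2	6-7	9-2	15-3	6-4	12-1	5-5	X-1	D8S1106
MM.1S										15
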
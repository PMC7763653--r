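sample	18-3	4-2	6-7	9-2	15-3	6-4	12-1	5-5	X-1
#1_HoxB8FL	16	19	19	17	22	19	15	16	23
#2_HoxB8FL	15	18	15, 18	15	20	18	16	17	24
#3_HoxB8FL	16	19	19	15	22	19	16	17	24
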
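sample	18-3	4-2	6-7	9-2	15-3	6-4	12-1	5-5	X-1
mPDAC06	17, 18	18	20	16	20, 22	17	16, 20	14, 16	20, 24
mPDAC09	17, 19	17, 19	20, 23	18, 22	20	18	16	16, 17	18, 25
mPDAC95	17	19, 19	17	18, 20	21	19	16	16, 17	26
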
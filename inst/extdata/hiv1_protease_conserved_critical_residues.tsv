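protein_id	position
HIV1-protease	9
HIV1-protease	15
HIV1-protease	23
HIV1-protease	24
HIV1-protease	25
HIV1-protease	26
HIV1-protease	27
HIV1-protease	28
HIV1-protease	29
HIV1-protease	31
HIV1-protease	32
HIV1-protease	33
HIV1-protease	47
HIV1-protease	49
HIV1-protease	51
HIV1-protease	52
HIV1-protease	74
HIV1-protease	81
HIV1-protease	84
HIV1-protease	86
HIV1-protease	87
HIV1-protease	90
HIV1-protease	97
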
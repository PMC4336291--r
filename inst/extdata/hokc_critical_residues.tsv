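protein_id	position
HokC	1
HokC	2
HokC	8
HokC	11
HokC	12
HokC	13
HokC	15
HokC	17
HokC	19
HokC	20
HokC	24
HokC	25
HokC	26
HokC	28
HokC	29
HokC	31
HokC	32
HokC	33
HokC	39
HokC	40
HokC	41
HokC	43
HokC	46
HokC	47
HokC	49
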
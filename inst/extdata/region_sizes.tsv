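region	length_kb	masked_kb
total	850	0
DEFB	234	69
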
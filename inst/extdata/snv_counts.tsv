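sample	region	known	novel
NA12716	CTRL	574	41
NA12716	DEFA	604	27
NA12716	DEFB	560	113
NA12760	CTRL	595	48
NA12760	DEFA	428	37
NA12760	DEFB	979	178
union	CTRL	771	77
union	DEFA	701	61
union	DEFB	1056	220
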
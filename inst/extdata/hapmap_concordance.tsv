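sample	truth_class	called_class	n
NA12716	het	homref_nocall	0
NA12716	het	homref	0
NA12716	het	het	237
NA12716	het	homvar	3
NA12716	het	not_covered	4
NA12716	homvar	homref_nocall	0
NA12716	homvar	homref	0
NA12716	homvar	het	5
NA12716	homvar	homvar	248
NA12716	homvar	not_covered	1
NA12716	homref	homref_nocall	827
NA12716	homref	homref	1
NA12716	homref	het	10
NA12716	homref	homvar	0
NA12716	homref	not_covered	1
NA12760	het	homref_nocall	5
NA12760	het	homref	2
NA12760	het	het	248
NA12760	het	homvar	0
NA12760	het	not_covered	8
NA12760	homvar	homref_nocall	0
NA12760	homvar	homref	0
NA12760	homvar	het	4
NA12760	homvar	homvar	212
NA12760	homvar	not_covered	1
NA12760	homref	homref_nocall	835
NA12760	homref	homref	1
NA12760	homref	het	4
NA12760	homref	homvar	0
NA12760	homref	not_covered	2
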
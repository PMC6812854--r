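ec	scop_ccs	description	nd
1.1.1.1	b.35.1.2	Alcohol dehydrogenase-like, N-terminal domain	0.0985401
1.1.1.1	c.2.1.1	Alcohol dehydrogenase-like, C-terminal domain	0.0985401
1.1.1.1	c.2.1.2	Tyrosine-dependent oxidoreductases	0.00364964
1.1.1.21	c.1.7.1	Aldo-keto reductases (NADP) domain	0.0985401
1.2.1.3	a.23.4.1	Mitochondrial import receptor subunit Tom20	0.781022
1.2.1.3	c.82.1.1	ALDH-like domain	0.0291971
2.3.1.9	c.95.1.1	Thiolase-related domain	0.0912409
2.6.1.1	c.67.1.1	AAT-like domain	0.0364963
2.6.1.1	c.67.1.3	Cystathionine synthase-like domain	0.0364963
4.2.1.17	a.100.1.3	HCDH C-domain-like domain	0.791971
4.2.1.17	c.14.1.3	Crotonase-like domain	0.0912409
4.2.1.17	c.2.1.6	6-phosphogluconate dehydrogenase-like, N-terminal domain	0.080292
4.2.1.17	c.95.1.1	Thiolase-related domain	0.0912409
4.2.1.17	d.38.1.4	MaoC-like domain	0.813869
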
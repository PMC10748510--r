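group	ADHD	Anxiety	Bipolar	Depression	Stress
Cohesion	19.66	22.26	19.90	24.13	23.25
Lexical	20.51	21.08	22.97	20.60	13.12
Morphosyntactic	19.40	21.98	18.86	22.97	16.92
Stylistic	21.30	20.42	19.50	22.09	31.76
Readability	19.13	14.27	18.78	10.21	14.96
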
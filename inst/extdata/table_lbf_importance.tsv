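group	ADHD	Anxiety	Bipolar	Depression	Stress
ANEW	21.08	18.75	19.32	18.35	17.84
ANEW-Emo	17.01	10.23	11.66	8.24	22.86
EmoLex	13.35	16.27	15.36	17.13	9.68
GALC	13.43	15.91	16.04	16.76	10.06
General Inquirer	12.42	14.10	13.87	15.43	9.71
LIWC	10.13	8.62	9.48	8.05	11.88
SenticNet	12.58	16.11	14.27	16.03	17.97
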
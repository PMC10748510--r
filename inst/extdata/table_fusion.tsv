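model	condition	accuracy	f1	precision	recall
Emotion-Infused	ADHD	68.02	67.12	67.77	66.58
Emotion-Infused	Anxiety	72.32	72.23	71.01	73.49
Emotion-Infused	Bipolar	71.49	70.10	69.75	70.45
Emotion-Infused	Depression	70.18	70.10	70.19	70.01
Emotion-Infused	Stress	81.12	81.05	81.23	81.00
Personality-Infused	ADHD	67.99	67.65	67.56	67.74
Personality-Infused	Anxiety	73.40	72.56	72.51	72.61
Personality-Infused	Bipolar	73.23	72.01	71.96	72.06
Personality-Infused	Depression	68.33	67.13	66.80	67.46
Personality-Infused	Stress	81.54	81.35	82.16	81.30
Emotion-Personality-Infused	ADHD	65.35	64.02	62.88	65.20
Emotion-Personality-Infused	Anxiety	72.36	72.88	72.63	73.13
Emotion-Personality-Infused	Bipolar	72.14	72.14	71.73	72.55
Emotion-Personality-Infused	Depression	71.42	71.46	71.46	71.46
Emotion-Personality-Infused	Stress	81.96	82.15	82.00	81.88
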
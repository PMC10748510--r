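model	type	condition	accuracy	f1	precision	recall
BiLSTM+GLFs	interpretable	ADHD	57.57	57.14	57.88	57.59
BiLSTM+GLFs	interpretable	Anxiety	62.95	62.94	62.96	62.94
BiLSTM+GLFs	interpretable	Bipolar	64.22	64.19	64.27	64.22
BiLSTM+GLFs	interpretable	Depression	62.58	62.59	62.60	62.59
BiLSTM+GLFs	interpretable	Stress	62.80	62.10	63.17	62.43
BiLSTM+LBFs	interpretable	ADHD	58.80	58.57	58.98	58.78
BiLSTM+LBFs	interpretable	Anxiety	64.81	64.81	64.81	64.80
BiLSTM+LBFs	interpretable	Bipolar	63.53	63.52	63.55	63.53
BiLSTM+LBFs	interpretable	Depression	62.21	62.20	62.22	62.21
BiLSTM+LBFs	interpretable	Stress	69.23	68.92	69.50	68.98
BiLSTM+GLFs+LBFs	interpretable	ADHD	58.85	58.45	59.13	58.83
BiLSTM+GLFs+LBFs	interpretable	Anxiety	62.80	62.52	63.21	62.81
BiLSTM+GLFs+LBFs	interpretable	Bipolar	62.23	61.72	62.81	62.25
BiLSTM+GLFs+LBFs	interpretable	Depression	62.92	62.89	62.95	62.92
BiLSTM+GLFs+LBFs	interpretable	Stress	71.03	70.78	71.10	70.83
MentalRoBERTa	reference	ADHD	64.28	64.72	64.68	64.65
MentalRoBERTa	reference	Anxiety	71.50	70.50	70.47	70.52
MentalRoBERTa	reference	Bipolar	71.55	71.83	72.04	71.62
MentalRoBERTa	reference	Depression	71.34	70.08	70.20	69.96
MentalRoBERTa	reference	Stress	82.22	81.62	81.65	81.59
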
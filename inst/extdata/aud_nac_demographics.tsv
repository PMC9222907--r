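Variable	CaseMean	CaseSD	ControlMean	ControlSD	PrintedT	PrintedP
DailyAlcoholGrams	124.7	45.8	11.3	4.9	3.24	0.035
AgeYears	49.3	5.6	48.3	5.7	0.16	0.880
PostmortemIntervalHours	43.2	5.6	35.0	16.0	0.61	0.575
BrainWeightGrams	1362.7	127.1	1611.7	87.8	-2.04	0.110
BrainPH	6.6	0.2	6.7	0.2	-0.64	0.557
RIN	6.1	0.5	7.4	2.4	-2.95	0.042
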
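family	te_class	sim	mel	hybrid
blood	LTR	5602.2	2904.2	1112.3
Burdock	LTR	627.6	1072.6	80.3
gypsy12	LTR	1574.0	1011.6	131.7
diver	LTR	1163.3	424.4	52.6
HMS-Beagle	LTR	1834.4	407.8	89.5
rover	LTR	51.0	1335.5	362.7
jockey	LINE	182.3	375.3	45.6
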
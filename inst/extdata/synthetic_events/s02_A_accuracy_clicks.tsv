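t_ms	x_px	y_px	hit	target_index
2863.01364210651	303.587299712477	225.156737950747	TRUE	1
4057.69282218413	539.687639752388	709.29191596585	TRUE	2
4849.20034685388	724.366668554752	269.318363784025	TRUE	3
6018.09104556019	302.23890293786	688.747038337101	TRUE	4
6810.34717621353	86.4189904254619	694.551337391895	TRUE	5
7863.19140839717	123.427812805335	223.813160837645	TRUE	6
8654.17652622273	712.352239414888	549.065887366397	TRUE	7
9259.21078893856	721.728284674765	361.137469288413	TRUE	8
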
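t_ms	x_px	y_px	hit	target_index
851.067840512857	98.1657814482534	61.8076056076376	TRUE	1
1250.11998406025	74.4240520003092	703.777562116769	FALSE	2
1550.11998406025	75.0887723145577	683.803767363699	TRUE	2
1944.28596438747	526.955000455513	181.516680771593	FALSE	3
2244.28596438747	515.674442400071	217.625142025399	TRUE	3
2934.78851649094	520.254687943621	724.585893806363	FALSE	4
3234.78851649094	512.512563795966	707.314822997628	TRUE	4
4001.40150250361	505.951999408902	66.4331665000761	TRUE	5
4581.82390982927	711.360963913471	279.155061516116	FALSE	6
4881.82390982927	706.99449690536	236.301566322551	TRUE	6
5469.165530647	532.780478724375	558.114513140569	TRUE	7
6087.34591486018	712.915066810157	45.9069947996333	TRUE	8
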
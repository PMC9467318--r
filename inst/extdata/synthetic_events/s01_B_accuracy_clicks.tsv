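t_ms	x_px	y_px	hit	target_index
2024.78776328034	109.43955226765	85.7095085880821	TRUE	1
3145.90636149048	105.287814936379	679.859221874517	TRUE	2
4026.36482362488	523.867649898566	207.899842269867	TRUE	3
5091.9512202804	522.50649576577	684.597793252822	TRUE	4
6151.85285795246	530.687721496316	65.6497398074177	TRUE	5
7193.47916005325	708.271959223077	248.823957986044	TRUE	6
8208.02975713025	520.346481560557	543.423923302886	TRUE	7
9088.07059173401	701.477891759483	67.785221398266	TRUE	8
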
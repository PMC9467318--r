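t_ms	x_px	y_px	hit	target_index
1282.81679040646	291.013126945351	233.149135053074	TRUE	1
2546.82524385416	529.672790310315	692.757828160791	TRUE	2
3583.07104858824	715.806494727262	263.046027095708	TRUE	3
4902.311973996	303.675052753706	682.398028348571	TRUE	4
5814.80720870801	95.5387229989262	675.476913785006	TRUE	5
6830.05419682537	113.65489337513	225.197981615187	TRUE	6
8266.517275615	698.898935717563	546.685159866347	TRUE	7
9300.54704490301	717.536540892531	352.09529560357	TRUE	8
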
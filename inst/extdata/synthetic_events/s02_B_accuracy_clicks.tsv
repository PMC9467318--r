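t_ms	x_px	y_px	hit	target_index
1898.16757861629	104.983800921607	82.6139590379241	TRUE	1
3443.09033823204	88.805912521105	683.952842034162	TRUE	2
4698.54553546333	520.225687153753	210.161046617868	TRUE	3
6000.19565423463	526.03428619463	674.365219299387	TRUE	4
7127.1080559093	533.214590858553	53.5391184662877	TRUE	5
7845.45026905445	706.811645378408	246.673281939392	TRUE	6
9213.25010719918	514.36771412061	561.959471679275	TRUE	7
10909.9227455211	693.755279961988	75.0787429498975	TRUE	8
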
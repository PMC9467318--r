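t_ms	x_px	y_px	hit	target_index
634.828316419532	300.134571181722	240.020684805817	TRUE	1
1307.38807978724	519.467708248562	712.242752845071	FALSE	2
1607.38807978724	551.718923385176	688.906685695406	TRUE	2
2707.95564576324	720.758691053745	254.173218452295	TRUE	3
3603.36948152442	302.819069904254	680.499626182635	TRUE	4
4223.33651917905	115.215077403799	677.804233755541	FALSE	5
4523.33651917905	108.768543175755	711.146119607168	FALSE	5
4823.33651917905	55.0389546317886	693.222334116415	FALSE	5
5123.33651917905	114.914460382316	697.294279715837	FALSE	5
5423.33651917905	97.8863448752013	688.712530062581	TRUE	5
6613.31444728695	142.025294603328	199.471499091205	FALSE	6
6913.31444728695	126.589829456084	236.115205131734	TRUE	6
7455.7066273801	731.822710451946	533.529367480356	FALSE	7
7755.7066273801	717.237500468462	538.2759525243	TRUE	7
8327.54913710045	706.563253138405	354.503627264357	TRUE	8
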
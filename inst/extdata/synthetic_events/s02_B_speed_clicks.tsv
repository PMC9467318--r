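t_ms	x_px	y_px	hit	target_index
1233.82610518468	132.320573067577	87.6684860535585	TRUE	1
1628.10344449361	77.3600104218018	689.992706876055	TRUE	2
2648.2287230071	520.282179886005	212.314786611197	TRUE	3
3403.6776080709	521.141212031853	682.788495885696	TRUE	4
4248.22597066217	555.160615957432	38.6879960255662	FALSE	5
4548.22597066217	513.215320586918	50.9424254929469	TRUE	5
5543.86459079859	736.283383465436	219.838110793126	FALSE	6
5843.86459079859	735.34770913712	261.77283242609	FALSE	6
6143.86459079859	693.601084840314	247.017462786585	TRUE	6
6687.82135551263	550.920502377283	538.253143813959	FALSE	7
6987.82135551263	503.52241709544	549.556616649265	TRUE	7
8018.00850754329	706.068866866603	55.43409431694	TRUE	8
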
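event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	151.393851995714	121.393851995714	0.55269858495517	-9.30199896041594	NA	NA
saccade	151.393851995714	181.393851995714	30	NA	NA	13.9805773249186	300
fixation	181.393851995714	284.876226943045	103.482374947331	0.379059682555404	4.67750002451199	NA	NA
saccade	284.876226943045	314.876226943045	30	NA	NA	17.7598363497275	300
fixation	314.876226943045	395.646535795246	80.7703088522015	-11.0716051505948	-8.89799488535992	NA	NA
saccade	395.646535795246	425.646535795246	30	NA	NA	17.7797417930437	300
fixation	425.646535795246	543.466720925184	117.820185129938	0.295879755761574	4.77312449569534	NA	NA
saccade	561.656447305058	573.466720925184	11.8102736201258	NA	NA	3.54308208603774	300
fixation	573.466720925184	650.653612730032	77.1868918048477	0.31279384590627	8.31616620896322	NA	NA
saccade	650.653612730032	680.653612730032	30	NA	NA	12.9107932790179	300
fixation	680.653612730032	793.004188365514	112.350575635483	5.11551994159251	-3.66809034467197	NA	NA
saccade	811.022246035499	881.067840512857	70.0455944773585	NA	NA	21.0136783432075	300
fixation	881.067840512857	997.348004935587	116.28016442273	-11.843326988563	8.74046268585271	NA	NA
saccade	997.348004935587	1027.34800493559	30.0000000000001	NA	NA	11.665825733488	300
fixation	1027.34800493559	1093.16309164595	65.8150867103657	-0.177512119233391	8.72454167335485	NA	NA
saccade	1533.84018590676	1580.11998406025	46.279798153484	NA	NA	13.8839394460452	300
fixation	1580.11998406025	1713.87962867528	133.759644615035	0.583775534054583	-5.13851050321873	NA	NA
saccade	1713.87962867528	1743.87962867528	30	NA	NA	18.1254612834024	300
fixation	1743.87962867528	1869.89666764977	126.017038974482	-11.8430804238264	8.0563975198861	NA	NA
saccade	1869.89666764977	1899.89666764977	30	NA	NA	12.9494581926823	300
fixation	1899.89666764977	1976.3511145929	76.4544469431369	0.576392103668826	4.38963196659304	NA	NA
saccade	2261.23838379769	2274.28596438747	13.0475805897743	NA	NA	3.91427417693229	300
fixation	2274.28596438747	2417.4927393175	143.206774930031	-0.301067816468031	8.20428875597166	NA	NA
saccade	2437.437405116	2447.4927393175	10.0553342014944	NA	NA	3.01660026044833	300
fixation	2447.4927393175	2540.99721522219	93.5044759046909	-0.0610488305725911	5.1972523382097	NA	NA
saccade	2540.99721522219	2570.99721522219	30	NA	NA	9.67489002285467	300
fixation	2570.99721522219	2696.4083017607	125.411086538513	0.435033325853318	-4.46491095208966	NA	NA
saccade	2696.4083017607	2726.4083017607	30	NA	NA	12.7276967426156	300
fixation	2726.4083017607	2836.64395797146	110.235656210753	-11.5678283734847	-8.69877153063416	NA	NA
saccade	3225.36411084817	3264.78851649094	39.4244056427662	NA	NA	11.8273216928298	300
fixation	3264.78851649094	3398.12807664836	133.339560157428	0.242996506552026	-9.32323456299837	NA	NA
saccade	3398.12807664836	3428.12807664836	30	NA	NA	21.6470891870776	300
fixation	3428.12807664836	3521.84141244778	93.7133357994162	-11.7769815853079	8.68000394968311	NA	NA
saccade	3521.84141244778	3551.84141244778	30	NA	NA	12.8130217737584	300
fixation	3551.84141244778	3641.40428709057	89.5628746427878	0.35879306702276	4.56946863628965	NA	NA
saccade	3641.40428709057	3671.40428709057	30	NA	NA	17.6049575051343	300
fixation	3671.40428709057	3786.7504429603	115.346155869734	-11.352260474567	-8.57533085642239	NA	NA
saccade	3971.90197977317	4031.40150250361	59.4995227304365	NA	NA	17.8498568191309	300
fixation	4031.40150250361	4109.8643394693	78.4628369656866	5.90787407805639	-4.02504035044247	NA	NA
saccade	4115.26657582519	4139.8643394693	24.5977636441081	NA	NA	7.37932909323243	300
fixation	4139.8643394693	4246.91366623449	107.049326765193	0.470616583420247	-9.01410126440711	NA	NA
saccade	4865.90099871406	4911.82390982927	45.9229111152118	NA	NA	13.7768733345635	300
fixation	4911.82390982927	5020.62108985252	108.797180023254	-0.0949157944068491	4.75115979400501	NA	NA
saccade	5037.19565083853	5050.62108985252	13.4254390139934	NA	NA	4.02763170419802	300
fixation	5050.62108985252	5152.73584909578	102.114759243253	0.4314411751512	8.74424951066036	NA	NA
saccade	5438.77158210975	5499.165530647	60.3939485372457	NA	NA	18.1181845611737	300
fixation	5499.165530647	5652.01603969131	152.85050904431	5.34337107459705	-8.69540520082069	NA	NA
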
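event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	170.847407676497	140.847407676497	-11.6433878147731	8.1758310809124	NA	NA
saccade	170.847407676497	200.847407676497	30	NA	NA	12.2329923617396	300
fixation	200.847407676497	345.491034142059	144.643626465562	0.586728147583019	8.44109636266079	NA	NA
saccade	345.491034142059	375.491034142059	30	NA	NA	17.6878986518397	300
fixation	375.491034142059	515.717046211298	140.226012069239	5.49921701421817	-8.55093741358085	NA	NA
saccade	515.717046211298	545.717046211298	30	NA	NA	24.2665743557247	300
fixation	545.717046211298	666.178047925907	120.461001714609	-11.5901697395784	8.67751264268001	NA	NA
saccade	666.178047925907	696.178047925907	30	NA	NA	11.6099021387843	300
fixation	696.178047925907	807.990113954177	111.812066028271	0.00780703500303215	8.15143051181436	NA	NA
saccade	807.990113954177	837.990113954177	30	NA	NA	20.2283453553069	300
fixation	837.990113954177	945.35441924679	107.364305292612	-11.5984184692852	-8.41605225887764	NA	NA
saccade	945.35441924679	975.35441924679	30	NA	NA	20.7338173587194	300
fixation	975.35441924679	1092.3231788214	116.968759574609	0.470594366271932	8.4430732059823	NA	NA
saccade	1110.34600012967	1122.3231788214	11.9771786917242	NA	NA	3.59315360751725	300
fixation	1122.3231788214	1233.00866928156	110.685490460163	0.789655261212685	4.86411344195396	NA	NA
saccade	1233.00866928156	1263.00866928156	30	NA	NA	14.3153739040887	300
fixation	1263.00866928156	1410.61740824858	147.608738967019	5.70301082145369	-8.58166162505173	NA	NA
saccade	1973.43408161257	2054.78776328034	81.3536816677707	NA	NA	24.4061045003312	300
fixation	2054.78776328034	2199.4642016564	144.676438376053	-12.2168541846282	7.98747761164038	NA	NA
saccade	2199.4642016564	2229.4642016564	30	NA	NA	16.7100064686085	300
fixation	2229.4642016564	2378.97857388573	149.514372229336	-11.3301142018884	-8.69898421775741	NA	NA
saccade	2378.97857388573	2408.97857388573	30	NA	NA	11.484179351849	300
fixation	2408.97857388573	2555.18869356339	146.210119677653	0.136965184099461	-9.32545507971968	NA	NA
saccade	2559.43254958651	2585.18869356339	25.7561439768784	NA	NA	7.72684319306353	300
fixation	2585.18869356339	2668.29686036139	83.108166798007	6.02372111119883	-4.32043655977866	NA	NA
saccade	2668.29686036139	2698.29686036139	30	NA	NA	13.4498466435633	300
fixation	2698.29686036139	2796.04629666282	97.7494363014284	0.486143330108698	7.93654541188746	NA	NA
saccade	2796.04629666282	2826.04629666282	30	NA	NA	17.1444042813332	300
fixation	2826.04629666282	2932.56829043734	106.521993774524	0.56815700401715	-9.20766270394824	NA	NA
saccade	2945.09779975153	2962.56829043734	17.47049068581	NA	NA	5.24114720574299	300
fixation	2962.56829043734	3077.04513765769	114.476847220343	5.74317805393531	-8.37773429428179	NA	NA
saccade	3077.04513765769	3107.04513765769	30	NA	NA	14.3819341003378	300
fixation	3107.04513765769	3255.56739335048	148.522255692792	-0.143601232565631	4.7442266147624	NA	NA
saccade	3255.56739335048	3285.56739335048	30	NA	NA	9.69046403065396	300
fixation	3285.56739335048	3389.28689073629	103.719497385815	0.496236706107226	-4.92509086588912	NA	NA
saccade	3402.89258313848	3419.28689073629	16.3943075978169	NA	NA	4.91829227934508	300
fixation	3419.28689073629	3556.67635746646	137.389466730165	5.28717194131793	-3.8130933312327	NA	NA
saccade	3556.67635746646	3586.67635746646	30	NA	NA	10.2178587821455	300
fixation	3586.67635746646	3698.00128392889	111.324926462428	-0.0646933363998752	4.89105373444964	NA	NA
saccade	3698.00128392889	3728.00128392889	30	NA	NA	10.6906028984412	300
fixation	3728.00128392889	3826.60733018547	98.6060462565842	5.70486917743861	-4.10900952816525	NA	NA
saccade	4011.39993615559	4056.36482362488	44.9648874692917	NA	NA	13.4894662407875	300
fixation	4056.36482362488	4154.38718672409	98.0223630992068	0.458437374994503	8.3184058428461	NA	NA
saccade	4154.38718672409	4184.38718672409	30	NA	NA	13.3614214851689	300
fixation	4184.38718672409	4293.86533340404	109.478146679946	5.89428844642577	-3.88729394182636	NA	NA
saccade	5096.86299394729	5121.9512202804	25.0882263331097	NA	NA	7.52646789993291	300
fixation	5121.9512202804	5249.32443110989	127.373210829488	0.241882217329544	-8.85700448369845	NA	NA
saccade	5249.32443110989	5279.32443110989	30	NA	NA	11.9138516741544	300
fixation	5279.32443110989	5391.92038269739	112.595951587504	-11.6646220550657	-8.43865328531855	NA	NA
saccade	5391.92038269739	5421.92038269739	30	NA	NA	16.814665118046	300
fixation	5421.92038269739	5508.05872323087	86.1383405334764	5.13430617677687	-9.16595878745252	NA	NA
saccade	5516.42521548797	5538.05872323087	21.6335077428932	NA	NA	6.49005232286796	300
fixation	5538.05872323087	5730.02640598017	191.967682749301	0.433080622487462	-4.69167030309435	NA	NA
saccade	5730.02640598017	5760.02640598017	30	NA	NA	9.2877472744361	300
fixation	5760.02640598017	5886.76320944446	126.736803464293	0.662213574634922	4.59325013404647	NA	NA
saccade	5886.76320944446	5916.76320944446	30	NA	NA	13.7304215625676	300
fixation	5916.76320944446	6022.66529764904	105.902088204581	5.3347947309947	-8.31765462212969	NA	NA
saccade	6033.87869429052	6052.66529764904	18.7866033585209	NA	NA	5.63598100755626	300
fixation	6052.66529764904	6212.82415443273	160.158856783692	0.715926855619988	-5.08805070409789	NA	NA
saccade	6227.09435573301	6242.82415443273	15.7297986997212	NA	NA	4.71893960991637	300
fixation	6242.82415443273	6365.13782590503	122.313671472296	5.36822717051136	-4.29780212162573	NA	NA
saccade	6378.37750276978	6395.13782590503	16.7603231352467	NA	NA	5.028096940574	300
fixation	6395.13782590503	6503.53582611552	108.398000210491	5.73452864640051	-9.3125386124666	NA	NA
saccade	6503.53582611552	6533.53582611552	30	NA	NA	19.0393772340581	300
fixation	6533.53582611552	6636.40425672552	102.868430610001	0.475856642745041	8.98621146011321	NA	NA
saccade	6636.40425672552	6666.40425672552	30	NA	NA	18.9993148893966	300
fixation	6666.40425672552	6770.26023235332	103.855975627794	5.44173989676245	-9.35265354767599	NA	NA
saccade	6777.95991464697	6800.26023235332	22.300317706343	NA	NA	6.6900953119029	300
fixation	6800.26023235332	6932.05861434951	131.798381996193	0.553214744132829	-4.78541180736349	NA	NA
saccade	6932.05861434951	6962.05861434951	30	NA	NA	13.2101630412918	300
fixation	6962.05861434951	7078.36780341659	116.309189067077	0.155624456469109	8.41876668054959	NA	NA
saccade	7078.36780341659	7108.36780341659	30	NA	NA	13.4966388671597	300
fixation	7108.36780341659	7188.02665961961	79.658856203022	0.351277137378133	-5.07645398229916	NA	NA
saccade	7189.08844971307	7223.47916005325	34.3907103401831	NA	NA	10.3172131020549	300
fixation	7223.47916005325	7358.69231247749	135.213152424234	-0.0806302193131299	5.23171473132064	NA	NA
saccade	7378.91081328677	7388.69231247749	9.78149919071772	NA	NA	2.93444975721532	300
fixation	7388.69231247749	7492.28580442302	103.593491945528	0.409818078937384	8.12488873997691	NA	NA
saccade	7492.28580442302	7522.28580442302	30	NA	NA	19.9891188303594	300
fixation	7522.28580442302	7614.47594246054	92.1901380375275	-10.809710949855	-8.41860061343086	NA	NA
saccade	7614.47594246054	7644.47594246054	30	NA	NA	16.9235088284851	300
fixation	7644.47594246054	7752.59909720547	108.123154744922	-12.2530301302957	8.44324924983107	NA	NA
saccade	7752.59909720547	7782.59909720547	30	NA	NA	21.7862082215922	300
fixation	7782.59909720547	7908.11849416764	125.519396962178	5.66744441678162	-3.94607925021783	NA	NA
saccade	7908.11849416764	7938.11849416764	30	NA	NA	17.5397444172497	300
fixation	7938.11849416764	8031.83622795223	93.7177337845906	-11.2702546981414	-8.50206244978958	NA	NA
saccade	8181.25545950765	8238.02975713025	56.7742976226014	NA	NA	17.0322892867804	300
fixation	8238.02975713025	8453.0066001364	214.976843006158	5.76193056607509	-8.5615895359114	NA	NA
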
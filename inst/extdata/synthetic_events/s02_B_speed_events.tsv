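event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	255.968904370567	225.968904370567	0.830677913365884	-4.78642360810828	NA	NA
saccade	255.968904370567	285.968904370567	30	NA	NA	9.21911446985319	300
fixation	285.968904370567	376.90410984383	90.9352054732635	0.587071023142156	4.42947175215336	NA	NA
saccade	394.261933549121	406.90410984383	12.6421762947097	NA	NA	3.7926528884129	300
fixation	406.90410984383	606.853197121567	199.949087277736	0.458618174804327	8.21994874030942	NA	NA
saccade	606.853197121567	636.853197121567	30	NA	NA	20.8334529711349	300
fixation	636.853197121567	816.324906497953	179.471709376386	-11.4049867430681	-8.90569405209765	NA	NA
saccade	816.324906497953	846.324906497953	30	NA	NA	18.0594152108957	300
fixation	846.324906497953	913.023536391614	66.6986298936607	0.254094437854175	4.88590860227854	NA	NA
saccade	913.023536391614	943.023536391614	30	NA	NA	10.0734010355085	300
fixation	943.023536391614	1063.14083539959	120.117299007977	0.337484065443927	-5.1871472693125	NA	NA
saccade	1075.03524825971	1093.14083539959	18.1055871398821	NA	NA	5.43167614196464	300
fixation	1093.14083539959	1199.78867043919	106.647835039597	5.68195866907472	-4.21776761080228	NA	NA
saccade	1199.78867043919	1263.82610518468	64.0374347454951	NA	NA	21.9510021841956	300
fixation	1263.82610518468	1385.7196355651	121.893530380419	-12.0402179259231	8.73487511669818	NA	NA
saccade	1385.7196355651	1415.7196355651	30	NA	NA	21.7762727508056	300
fixation	1415.7196355651	1577.01139685206	161.291761286961	0.109321343220337	-9.33705755429806	NA	NA
saccade	1577.01139685206	1607.01139685206	30	NA	NA	17.6098724505115	300
fixation	1607.01139685206	1748.10076883167	141.089371979607	0.601341973006798	8.26594001495557	NA	NA
saccade	1767.70018812057	1778.10076883167	10.4005807110995	NA	NA	3.12017421332984	300
fixation	1778.10076883167	1865.43718744994	87.336418618273	0.782043183965135	5.15100274530042	NA	NA
saccade	1865.43718744994	1895.43718744994	30	NA	NA	10.1529924893974	300
fixation	1895.43718744994	2016.56911833288	121.131930882941	5.01518873391637	-4.07741723011728	NA	NA
saccade	2029.18034871629	2046.56911833288	17.388769616593	NA	NA	5.21663088497789	300
fixation	2046.56911833288	2165.34364198495	118.774523652063	-0.146738790247211	-4.83090380955156	NA	NA
saccade	2171.24366019736	2195.34364198495	24.0999817875912	NA	NA	7.22999453627737	300
fixation	2195.34364198495	2329.48836619028	134.144724205335	5.69597966618037	-9.08947892730174	NA	NA
saccade	2329.48836619028	2359.48836619028	30	NA	NA	14.8372144043704	300
fixation	2359.48836619028	2466.83691679899	107.34855060871	0.503579476198238	4.80951066001466	NA	NA
saccade	2466.83691679899	2496.83691679899	30	NA	NA	14.8073942535276	300
fixation	2496.83691679899	2601.94441650345	105.107499704463	5.66508644169879	-9.06916976805531	NA	NA
saccade	2617.15411087371	2678.2287230071	61.0746121333895	NA	NA	18.3223836400168	300
fixation	2678.2287230071	2837.9069932002	159.678270193101	0.418218157909786	8.48588977227452	NA	NA
saccade	2837.9069932002	2867.9069932002	30	NA	NA	13.7488237012372	300
fixation	2867.9069932002	3052.36237989458	184.455386694378	5.39331847561965	-4.33122885854208	NA	NA
saccade	3064.04516352508	3082.36237989458	18.3172163694994	NA	NA	5.49516491084982	300
fixation	3082.36237989458	3191.01153136132	108.649151466739	-0.0352633753727269	-5.18406910413986	NA	NA
saccade	3191.01153136132	3221.01153136132	30	NA	NA	11.6793621386656	300
fixation	3221.01153136132	3395.47150603188	174.459974670555	-11.2490569877519	-8.44877931870077	NA	NA
saccade	3395.47150603188	3425.47150603188	30	NA	NA	16.7839450485727	300
fixation	3425.47150603188	3600.60544435247	175.133938320597	5.51682773294338	-9.22718854646117	NA	NA
saccade	3613.34616647371	3630.60544435247	17.2592778787591	NA	NA	5.17778336362774	300
fixation	3630.60544435247	3833.74777398332	203.142329630844	0.340912972175387	-9.36628186019044	NA	NA
saccade	3833.74777398332	3863.74777398332	30	NA	NA	21.2504467669233	300
fixation	3863.74777398332	3977.97687002981	114.229096046493	-12.1474269723164	7.82740457479638	NA	NA
saccade	3977.97687002981	4007.97687002981	30	NA	NA	24.9085291652309	300
fixation	4007.97687002981	4127.74411705728	119.767247027473	5.79398533580287	-9.45092143107654	NA	NA
saccade	4127.74411705728	4157.74411705728	30	NA	NA	15.6226708803033	300
fixation	4157.74411705728	4277.17002925335	119.425912196065	-0.168415608420026	4.98921777928456	NA	NA
saccade	4277.17002925335	4307.17002925335	30	NA	NA	14.9031454259095	300
fixation	4307.17002925335	4500.61632968055	193.446300427206	5.60453364391764	-8.75038922076244	NA	NA
saccade	4508.06913707661	4530.61632968055	22.5471926039407	NA	NA	6.7641577811822	300
fixation	4530.61632968055	4629.10440037432	98.4880706937683	0.453888968627524	-4.36579232736012	NA	NA
saccade	4640.76046923342	4659.10440037432	18.3439311408992	NA	NA	5.50317934226977	300
fixation	4659.10440037432	4804.47950064246	145.375100268137	5.9005137162685	-3.57886048052102	NA	NA
saccade	6140.39491911465	6173.86459079859	33.4696716839362	NA	NA	10.0409015051809	300
fixation	6173.86459079859	6314.11814124128	140.253550442698	0.129881263607354	4.63816478006066	NA	NA
saccade	6331.8650390966	6344.11814124128	12.2531021446883	NA	NA	3.67593064340648	300
fixation	6344.11814124128	6496.35772297693	152.239581735645	0.168899907881258	8.31388833339459	NA	NA
saccade	6496.35772297693	6526.35772297693	30	NA	NA	11.5225369552177	300
fixation	6526.35772297693	6758.50347711726	232.145754140335	-11.3529577422561	8.18877169049928	NA	NA
saccade	6758.50347711726	6788.50347711726	30	NA	NA	21.0664316520782	300
fixation	6788.50347711726	6895.61878734064	107.115310223377	5.60618503439508	-4.30850876697795	NA	NA
saccade	6906.79669045553	6925.61878734064	18.8220968851091	NA	NA	5.64662906553272	300
fixation	6925.61878734064	7054.52298185781	128.904194517168	0.0844463794322907	-5.48953460497161	NA	NA
saccade	7054.52298185781	7084.52298185781	30	NA	NA	18.0144017867125	300
fixation	7084.52298185781	7202.8174279148	118.294446056996	-11.6406309448429	8.18676728818942	NA	NA
saccade	7202.8174279148	7232.8174279148	30	NA	NA	16.6692868806794	300
fixation	7232.8174279148	7373.15216121564	140.334733300833	-11.4647236655708	-8.48159141143931	NA	NA
saccade	7373.15216121564	7403.15216121564	30	NA	NA	17.1904183017655	300
fixation	7403.15216121564	7620.47058662363	217.318425407988	5.71667679175658	-9.03833166921245	NA	NA
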
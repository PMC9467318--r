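event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	147.730283236521	117.730283236521	6.23661421591097	-1.17606117027764	NA	NA
saccade	156.802523030831	177.730283236521	20.92776020569	NA	NA	6.278328061707	300
fixation	177.730283236521	273.558713537005	95.8284303004838	5.17040789411124	5.01107122928937	NA	NA
saccade	285.036336577553	303.558713537005	18.5223769594514	NA	NA	5.55671308783541	300
fixation	303.558713537005	466.465935404991	162.907221867986	1.12445575009192	8.8199203453383	NA	NA
saccade	472.560868463078	496.465935404991	23.9050669419125	NA	NA	7.17152008257374	300
fixation	496.465935404991	633.160335002739	136.694399597748	-6.04703975012499	8.80114309507994	NA	NA
saccade	640.164612399743	663.160335002739	22.9957226029964	NA	NA	6.89871678089892	300
fixation	663.160335002739	790.163998814809	127.00366381207	0.84971526235476	8.63663315345992	NA	NA
saccade	790.163998814809	820.163998814809	30	NA	NA	13.2176018770005	300
fixation	820.163998814809	930.385458760745	110.221459945936	5.45762389524602	-3.75175566066002	NA	NA
saccade	930.385458760745	960.385458760745	30	NA	NA	11.2772405952782	300
fixation	960.385458760745	1104.73874976682	144.353291006076	-5.81931673611297	-3.83400795908558	NA	NA
saccade	1104.73874976682	1134.73874976682	30	NA	NA	11.8637418224156	300
fixation	1134.73874976682	1284.82378822562	150.085038458801	6.04163203030535	-3.57658925476819	NA	NA
saccade	1284.82378822562	1314.82378822562	30	NA	NA	17.827929977575	300
fixation	1314.82378822562	1446.72693162679	131.903143401164	-6.48328987786937	9.11046786969691	NA	NA
saccade	1446.72693162679	1476.72693162679	30	NA	NA	12.9025424983585	300
fixation	1476.72693162679	1689.09794017987	212.371008553085	5.68168411304924	4.8105829035354	NA	NA
saccade	2872.06592116736	2893.01364210651	20.9477209391439	NA	NA	6.28431628174316	300
fixation	2893.01364210651	3111.54139835291	218.527756246404	0.691666965976302	8.63057766804755	NA	NA
saccade	3111.54139835291	3141.54139835291	30	NA	NA	14.6792679299463	300
fixation	3141.54139835291	3213.17216837112	71.6307700182051	-5.88978851888796	-4.49060180103598	NA	NA
saccade	3213.17216837112	3243.17216837112	30	NA	NA	13.2926859208452	300
fixation	3243.17216837112	3411.82459012054	168.652421749426	-6.42428861967135	8.79133362391244	NA	NA
saccade	3411.82459012054	3441.82459012054	30	NA	NA	15.3564919072084	300
fixation	3441.82459012054	3536.59325708731	94.7686669667632	5.74055925780608	-0.580876351007494	NA	NA
saccade	3536.59325708731	3566.59325708731	30	NA	NA	17.1517139802502	300
fixation	3566.59325708731	3721.15397252409	154.560715436783	-10.9802235016524	-4.40144127930101	NA	NA
saccade	4033.78113705584	4087.69282218413	53.911685128292	NA	NA	16.1735055384876	300
fixation	4087.69282218413	4253.52864962727	165.835827443142	5.13754957230122	-3.05992253547884	NA	NA
saccade	4253.52864962727	4283.52864962727	30	NA	NA	16.163421662319	300
fixation	4283.52864962727	4408.06373060314	124.535080975865	-10.9745403305869	-4.34707396214773	NA	NA
saccade	4408.06373060314	4438.06373060314	30	NA	NA	16.8183810377426	300
fixation	4438.06373060314	4524.81999551547	86.7562649123283	5.55715239371929	-1.25497493400789	NA	NA
saccade	4524.81999551547	4554.81999551547	30	NA	NA	20.5759485262894	300
fixation	4554.81999551547	4697.74200781433	142.922012298865	-12.5047594380651	8.60083547089323	NA	NA
saccade	4697.74200781433	4727.74200781433	30	NA	NA	20.2739420759613	300
fixation	4727.74200781433	4860.00198892595	132.259981111622	5.68990712883438	-0.342700508728245	NA	NA
saccade	4860.00198892595	4890.00198892595	30	NA	NA	10.7539014548411	300
fixation	4890.00198892595	5021.22226601813	131.220277092176	1.07057213523122	9.36853734837871	NA	NA
saccade	5021.22226601813	5051.22226601813	30	NA	NA	15.7443711805877	300
fixation	5051.22226601813	5181.06416728155	129.841901263424	-5.82419275119661	-4.78587684059441	NA	NA
saccade	5181.06416728155	5211.06416728155	30	NA	NA	13.4819940394417	300
fixation	5211.06416728155	5385.90030723029	174.836139948733	-5.84926313066004	8.6960938890732	NA	NA
saccade	5385.90030723029	5415.90030723029	30	NA	NA	14.3347997895129	300
fixation	5415.90030723029	5531.94346143302	116.043154202736	5.47329212694656	-0.0951646922599528	NA	NA
saccade	5548.45125288663	5561.94346143302	13.492208546391	NA	NA	4.04766256391729	300
fixation	5561.94346143302	5682.50338106337	120.559919630348	5.53161391721774	-4.14240706208623	NA	NA
saccade	5682.50338106337	5712.50338106337	30	NA	NA	11.9723611224893	300
fixation	5712.50338106337	5881.61765977344	169.114278710073	-6.41424175539497	-4.93862505761177	NA	NA
saccade	5881.61765977344	5911.61765977344	30	NA	NA	13.3474734416869	300
fixation	5911.61765977344	6041.91252022922	130.294860455771	6.20862927711235	-0.60063310588757	NA	NA
saccade	6041.91252022922	6071.91252022922	30	NA	NA	20.3511729707133	300
fixation	6071.91252022922	6171.27409729125	99.3615770620372	-12.1767422394271	8.125669403349	NA	NA
saccade	6171.27409729125	6201.27409729125	30	NA	NA	13.9920364210962	300
fixation	6201.27409729125	6340.98666110442	139.712563813165	-6.07844074175242	-4.46749549086014	NA	NA
saccade	6824.58485060377	6840.34717621353	15.7623256097599	NA	NA	4.72869768292796	300
fixation	6840.34717621353	6956.95020142269	116.603025209162	-10.8057143281209	-4.58353951764067	NA	NA
saccade	6956.95020142269	6986.95020142269	30	NA	NA	17.4642601504506	300
fixation	6986.95020142269	7093.93417732688	106.983975904195	6.27285500595983	-0.933491284587489	NA	NA
saccade	7093.93417732688	7123.93417732688	30	NA	NA	20.4127889611006	300
fixation	7123.93417732688	7255.54203183868	131.607854511796	-11.8313273048792	8.49627732478636	NA	NA
saccade	7255.54203183868	7285.54203183868	30	NA	NA	19.7582239160202	300
fixation	7285.54203183868	7399.39462675798	113.852594919298	5.51097041364728	-0.971146937260047	NA	NA
saccade	7421.68320823754	7429.39462675798	7.71141852043711	NA	NA	2.31342555613113	300
fixation	7429.39462675798	7521.3571430868	91.9625163288265	5.67293342766546	-3.2788960106757	NA	NA
saccade	7521.3571430868	7551.3571430868	30	NA	NA	12.890804523452	300
fixation	7551.3571430868	7732.73516727278	181.378024185977	1.1562804694705	8.79474003308012	NA	NA
saccade	7873.53597590708	7893.19140839717	19.6554324900897	NA	NA	5.89662974702692	300
fixation	7893.19140839717	8073.83259966965	180.641191272483	5.49577809937084	4.80237197719999	NA	NA
saccade	8073.83259966965	8103.83259966965	30	NA	NA	14.6310602514613	300
fixation	8103.83259966965	8238.45208774544	134.619488075787	-5.92935125837364	-4.33734044938628	NA	NA
saccade	8238.45208774544	8268.45208774544	30	NA	NA	11.3066688122322	300
fixation	8268.45208774544	8388.9014937979	120.449406052461	5.30994135348126	-3.10483843534774	NA	NA
saccade	8388.9014937979	8418.9014937979	30	NA	NA	12.2551621003017	300
fixation	8418.9014937979	8533.34841474252	114.44692094462	1.1208049554828	8.41211143619535	NA	NA
saccade	8533.34841474252	8563.34841474252	30	NA	NA	13.1784598859722	300
fixation	8563.34841474252	8677.94520353085	114.596788788338	5.91772141562212	-3.8623090161365	NA	NA
saccade	8696.41606060552	8707.94520353085	11.5291429253331	NA	NA	3.45874287759994	300
fixation	8707.94520353085	8840.80457695356	132.859373422702	5.33409692525255	-0.453161799076326	NA	NA
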
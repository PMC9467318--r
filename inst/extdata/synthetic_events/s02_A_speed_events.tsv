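event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	143.659370829	113.659370829	5.98875814185405	-0.932357157882117	NA	NA
saccade	143.659370829	173.659370829	30	NA	NA	11.3631764198753	300
fixation	173.659370829	321.297590624566	147.638219795566	0.585420209810887	9.06392802919378	NA	NA
saccade	321.297590624566	351.297590624566	30	NA	NA	15.4918430957132	300
fixation	351.297590624566	485.31863766855	134.021047043983	-6.12859718277172	-4.89741764213377	NA	NA
saccade	485.31863766855	515.31863766855	30	NA	NA	11.7542020652901	300
fixation	515.31863766855	665.193287762119	149.874650093569	5.52448763560315	-3.3589507404971	NA	NA
saccade	954.261568180557	997.230849918112	42.9692817375559	NA	NA	12.8907845212668	300
fixation	997.230849918112	1135.18242297046	137.951573052343	0.53782708900178	8.52825003036147	NA	NA
saccade	1135.18242297046	1165.18242297046	30	NA	NA	12.5611612421113	300
fixation	1165.18242297046	1263.45969659603	98.2772736255724	-12.0227321215005	8.40527007351679	NA	NA
saccade	1274.3934363028	1293.45969659603	19.0662602932313	NA	NA	5.7198780879694	300
fixation	1293.45969659603	1431.58371962904	138.124023033017	-6.30321801583703	8.46979709382117	NA	NA
saccade	2363.70152876344	2419.43199605322	55.7304672897803	NA	NA	16.7191401869341	300
fixation	2419.43199605322	2515.19767490174	95.7656788485256	5.51231046341996	-3.35910544809798	NA	NA
saccade	2876.69909293633	2931.98440421825	55.2853112819209	NA	NA	16.5855933845763	300
fixation	2931.98440421825	3064.91207861336	132.927674395103	-5.94931901688386	8.62892848473397	NA	NA
saccade	3064.91207861336	3094.91207861336	30	NA	NA	16.7210736615286	300
fixation	3094.91207861336	3242.05999602963	147.147917416269	5.47584386325643	-3.58008284118954	NA	NA
saccade	3242.05999602963	3272.05999602963	30	NA	NA	16.4979465118328	300
fixation	3272.05999602963	3419.26903903138	147.209043001749	-10.9989717167296	-4.45340449599134	NA	NA
saccade	3419.26903903138	3449.26903903138	30	NA	NA	16.6071441192852	300
fixation	3449.26903903138	3606.31893185615	157.049892824776	5.59950460979475	-3.91691643785776	NA	NA
saccade	3606.31893185615	3636.31893185615	30	NA	NA	12.046298882789	300
fixation	3636.31893185615	3733.2447553901	96.9258235339512	-6.44138231209825	-4.27796893773668	NA	NA
saccade	3733.2447553901	3763.2447553901	30	NA	NA	12.7741349051015	300
fixation	3763.2447553901	3873.68090882278	110.436153432677	5.73867212728469	-0.427670711962325	NA	NA
saccade	4421.50145931139	4486.33846521789	64.8370059065031	NA	NA	19.4511017719509	300
fixation	4486.33846521789	4648.46897051742	162.130505299532	-11.4278225824124	8.71873948683893	NA	NA
saccade	5032.97574975748	5079.01683102071	46.0410812632273	NA	NA	13.8123243789682	300
fixation	5079.01683102071	5206.67256767659	127.655736655876	-10.9312803000631	-5.08465685289131	NA	NA
saccade	5220.41777904026	5236.67256767659	16.2547886363315	NA	NA	4.87643659089944	300
fixation	5236.67256767659	5342.70336289175	106.030795215159	-6.11455571829546	-4.32386901882802	NA	NA
saccade	5796.71326813109	5845.86145847879	49.148190347702	NA	NA	14.7444571043106	300
fixation	5845.86145847879	6061.74291127604	215.881452797244	5.35810236372809	4.93772543535938	NA	NA
saccade	6454.94940022563	6473.06895860724	18.1195583816078	NA	NA	5.43586751448234	300
fixation	6473.06895860724	6573.45990516853	100.390946561293	6.12274995682579	-0.444093002062521	NA	NA
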
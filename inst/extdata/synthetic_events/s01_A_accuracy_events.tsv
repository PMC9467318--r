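event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	160.162349015748	130.162349015748	5.84666034409948	-0.571613329519727	NA	NA
saccade	182.009495335327	190.162349015748	8.15285368042078	NA	NA	2.44585610412624	300
fixation	190.162349015748	273.823525610033	83.6611765942848	5.25351047751439	-2.94445662773005	NA	NA
saccade	273.823525610033	303.823525610033	30	NA	NA	11.3429082155755	300
fixation	303.823525610033	396.131861772004	92.3083361619709	-6.01068222347928	-4.27844672583819	NA	NA
saccade	396.131861772004	426.131861772004	30	NA	NA	11.9936206021041	300
fixation	426.131861772004	531.351438608431	105.219576836427	5.96619078096762	-3.6448473393426	NA	NA
saccade	533.739935665876	561.351438608431	27.6115029425544	NA	NA	8.28345088276632	300
fixation	561.351438608431	649.690069472113	88.3386308636824	5.39307088430159	4.61875309335305	NA	NA
saccade	653.110007626981	679.690069472113	26.580061845132	NA	NA	7.97401855353959	300
fixation	679.690069472113	772.324825153761	92.6347556816477	5.50389145956339	-3.35449534704389	NA	NA
saccade	775.752762437651	802.324825153761	26.5720627161096	NA	NA	7.97161881483289	300
fixation	802.324825153761	885.576495836683	83.2516706829222	5.6086511844213	4.61643508352978	NA	NA
saccade	1291.68689585555	1312.81679040646	21.1298945509095	NA	NA	6.33896836527285	300
fixation	1312.81679040646	1440.02134107992	127.204550673457	0.834305968524285	8.78634487816218	NA	NA
saccade	1440.02134107992	1470.02134107992	30	NA	NA	14.775989026205	300
fixation	1470.02134107992	1669.22184290986	199.200501829939	-5.94459776938629	-4.34287123761084	NA	NA
saccade	2539.47095534147	2576.82524385416	37.3542885126876	NA	NA	11.2062865538063	300
fixation	2576.82524385416	2674.80585975755	97.9806159033938	5.17959382565412	-2.98890680571032	NA	NA
saccade	2697.028095873	2704.80585975755	7.77776388455601	NA	NA	2.3333291653668	300
fixation	2704.80585975755	2838.63130527375	133.825445516196	5.82562828998842	-0.7467951972386	NA	NA
saccade	2838.63130527375	2868.63130527375	30	NA	NA	19.8047021682934	300
fixation	2868.63130527375	2998.59966660853	129.968361334785	-11.388236776922	9.04652280193856	NA	NA
saccade	2998.59966660853	3028.59966660853	30	NA	NA	14.1694004287938	300
fixation	3028.59966660853	3112.3010463832	83.7013797746672	-11.1204695720305	-5.1203473264803	NA	NA
saccade	3112.3010463832	3142.3010463832	30	NA	NA	13.2487801164922	300
fixation	3142.3010463832	3263.77023262484	121.46918624164	-11.8796701393713	8.10666250468371	NA	NA
saccade	3593.52589657757	3613.07104858824	19.5451520106738	NA	NA	5.86354560320214	300
fixation	3613.07104858824	3688.38609304693	75.3150444586872	-6.06091892526505	8.83005821186516	NA	NA
saccade	3688.38609304693	3718.38609304693	30	NA	NA	12.869815763275	300
fixation	3718.38609304693	3803.74310954774	85.3570165008091	5.9599489980019	4.23322319720423	NA	NA
saccade	3803.74310954774	3833.74310954774	30	NA	NA	15.2635279833781	300
fixation	3833.74310954774	3926.56572496433	92.8226154165886	-6.74874275875491	-4.22044111663676	NA	NA
saccade	3926.56572496433	3956.56572496433	30	NA	NA	14.7408581866237	300
fixation	3956.56572496433	4075.4494333255	118.883708361172	0.785201644575048	8.44970417872914	NA	NA
saccade	4075.4494333255	4105.4494333255	29.9999999999995	NA	NA	14.969710160487	300
fixation	4105.4494333255	4196.38959971392	90.9401663884173	-6.24243303668638	-4.76788157191829	NA	NA
saccade	4884.80929681541	4932.311973996	47.5026771805884	NA	NA	14.2508031541765	300
fixation	4932.311973996	5094.76933613836	162.457362142361	-11.7829847240701	8.36176722530845	NA	NA
saccade	5094.76933613836	5124.76933613836	30	NA	NA	13.8337497891843	300
fixation	5124.76933613836	5232.86191822892	108.09258209056	-6.05003198939335	-4.22814485427808	NA	NA
saccade	5828.52643711395	5844.80720870801	16.2807715940633	NA	NA	4.88423147821898	300
fixation	5844.80720870801	5919.07015783738	74.2629491293656	-10.864537257441	-5.05049280786404	NA	NA
saccade	6797.69946162858	6860.05419682537	62.3547351967961	NA	NA	18.7064205590388	300
fixation	6860.05419682537	6981.07186501402	121.017668188646	5.27363518685633	4.4093993844262	NA	NA
saccade	6981.07186501402	7011.07186501402	30	NA	NA	18.3266899835184	300
fixation	7011.07186501402	7109.90769573252	98.8358307185053	-10.7373586523344	-4.50775498417087	NA	NA
saccade	8238.46123424644	8296.517275615	58.0560413685544	NA	NA	17.4168124105663	300
fixation	8296.517275615	8490.87353872663	194.356263111633	6.22048892004629	-0.535757972998925	NA	NA
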
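event	onset	offset	duration	x_deg	y_deg	amplitude	peak_velocity
fixation	30	194.894718313283	164.894718313283	-6.60528713826024	-4.13890825894042	NA	NA
saccade	194.894718313283	224.894718313283	30	NA	NA	13.0183156583599	300
fixation	224.894718313283	315.654963040275	90.7602447269928	-5.91695879769278	8.86119738202538	NA	NA
saccade	642.685071598048	664.828316419532	22.1432448214842	NA	NA	6.64297344644525	300
fixation	664.828316419532	775.618132421378	110.789816001846	0.725997610111276	8.87624311868959	NA	NA
saccade	784.250423171357	805.618132421378	21.3677092500216	NA	NA	6.41031277500649	300
fixation	805.618132421378	935.888283261631	130.270150840253	5.33601119296606	4.4220445780646	NA	NA
saccade	935.888283261631	965.888283261631	30	NA	NA	17.8802074063852	300
fixation	965.888283261631	1085.62222845983	119.733945198202	-12.1122070626082	8.32864112764554	NA	NA
saccade	1095.10136096168	1115.62222845983	20.5208674981515	NA	NA	6.15626024944545	300
fixation	1115.62222845983	1235.16165590008	119.539427440252	-5.97793389566356	8.84848049918703	NA	NA
saccade	1235.16165590008	1265.16165590008	30	NA	NA	12.8402996146767	300
fixation	1265.16165590008	1333.87939932532	68.7177434252392	-5.72470746568466	-3.98932190503409	NA	NA
saccade	1333.87939932532	1363.87939932532	30	NA	NA	14.0677245155711	300
fixation	1363.87939932532	1460.48753956393	96.6081402386026	-11.9722217589342	8.61502013259893	NA	NA
saccade	1564.99227990142	1637.38807978724	72.3957998858182	NA	NA	21.7187399657455	300
fixation	1637.38807978724	1800.59678271306	163.208702925826	6.0482234753065	-3.50798359005175	NA	NA
saccade	1800.59678271306	1830.59678271306	30	NA	NA	13.7404422325931	300
fixation	1830.59678271306	1940.98009263152	110.383309918458	0.334068614065252	8.98794322507414	NA	NA
saccade	2716.52579746017	2737.95564576324	21.4298483030697	NA	NA	6.4289544909209	300
fixation	2737.95564576324	2889.92181244454	151.966166681295	-6.05705688873025	8.29154488084222	NA	NA
saccade	2889.92181244454	2919.92181244454	30	NA	NA	13.6927315027629	300
fixation	2919.92181244454	3050.90908840405	130.987275959512	-11.0582087663317	-4.45519493386806	NA	NA
saccade	3050.90908840405	3080.90908840405	30	NA	NA	17.8883440362477	300
fixation	3080.90908840405	3196.11861025649	115.209521852441	0.791186150381113	8.94572639516524	NA	NA
saccade	3592.31125468164	3633.36948152442	41.0582268427825	NA	NA	12.3174680528347	300
fixation	3633.36948152442	3716.05862648621	82.6891449617938	-11.5261220994328	8.88298317504042	NA	NA
saccade	3716.05862648621	3746.05862648621	30	NA	NA	16.8266018287753	300
fixation	3746.05862648621	3842.53905353919	96.4804270529717	4.82826643306015	4.9246369506168	NA	NA
saccade	3842.53905353919	3872.53905353919	30	NA	NA	11.6127448958857	300
fixation	3872.53905353919	4031.12693198244	158.587878443256	-6.1904995189157	8.59105767286035	NA	NA
saccade	4031.12693198244	4061.12693198244	30	NA	NA	12.2372718814149	300
fixation	4061.12693198244	4197.66343079756	136.53649881512	5.43222580604968	4.76181765425655	NA	NA
saccade	5389.27853407293	5453.33651917905	64.0579851061201	NA	NA	19.217395531836	300
fixation	5453.33651917905	5580.26776206681	126.931242887753	-11.0469307375163	-5.12482437626518	NA	NA
saccade	5593.74486331686	5610.26776206681	16.5228987499442	NA	NA	4.95686962498327	300
fixation	5610.26776206681	5694.83499784296	84.5672357761496	-6.15814514388043	-4.30608638487827	NA	NA
saccade	5694.83499784296	5724.83499784296	30	NA	NA	11.6820450555802	300
fixation	5724.83499784296	5849.23472256063	124.399724717669	5.50738104715646	-3.68505871493316	NA	NA
saccade	6913.15989573403	6943.31444728695	30.1545515529246	NA	NA	9.04636546587739	300
fixation	6943.31444728695	7020.34736743643	77.0329201494797	5.43499254896822	5.36101712200018	NA	NA
saccade	7021.04546028843	7050.34736743643	29.301907148004	NA	NA	8.79057214440121	300
fixation	7050.34736743643	7188.7950497948	138.447682358374	5.8813285542031	-3.41821648899079	NA	NA
saccade	7188.7950497948	7218.7950497948	30	NA	NA	13.2173486359812	300
fixation	7218.7950497948	7373.53819816056	154.743148365752	0.741561293107566	8.75885612583926	NA	NA
saccade	7748.84527989187	7785.7066273801	36.8613474882337	NA	NA	11.0584042464701	300
fixation	7785.7066273801	7961.78199661581	176.075369235714	5.93098079321026	-1.00629772498674	NA	NA
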
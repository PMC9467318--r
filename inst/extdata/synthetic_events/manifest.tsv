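subject	test_type	instruction	start_t	end_t	events_file	clicks_file	layout_file
s01	A	accuracy	0	9300.54704490301	s01_A_accuracy_events.tsv	s01_A_accuracy_clicks.tsv	layout_A.tsv
s01	B	accuracy	0	9088.07059173401	s01_B_accuracy_events.tsv	s01_B_accuracy_clicks.tsv	layout_B.tsv
s01	A	speed	0	8327.54913710045	s01_A_speed_events.tsv	s01_A_speed_clicks.tsv	layout_A.tsv
s01	B	speed	0	6087.34591486018	s01_B_speed_events.tsv	s01_B_speed_clicks.tsv	layout_B.tsv
s02	A	accuracy	0	9259.21078893856	s02_A_accuracy_events.tsv	s02_A_accuracy_clicks.tsv	layout_A.tsv
s02	B	accuracy	0	10909.9227455211	s02_B_accuracy_events.tsv	s02_B_accuracy_clicks.tsv	layout_B.tsv
s02	A	speed	0	6954.03986067899	s02_A_speed_events.tsv	s02_A_speed_clicks.tsv	layout_A.tsv
s02	B	speed	0	8018.00850754329	s02_B_speed_events.tsv	s02_B_speed_clicks.tsv	layout_B.tsv
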
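# version=A circle_diameter=1.35 aoi_diameter=3.25
label	x_px	y_px
1	291.997055171402	230.312352056645
2	539.901958592546	693.41692866316
3	708.844714012037	257.983232308688
4	297.556666288548	694.955314811259
5	83.6595155309044	689.809197866513
6	118.372628598998	219.603517174409
7	704.294366012829	548.341216125238
8	718.185243705606	360.044429747236
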
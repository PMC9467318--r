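# version=B circle_diameter=1.35 aoi_diameter=3.25
label	x_px	y_px
1	108.93276056823	79.9469966920409
A	93.6739200888772	677.706697523655
2	525.955600026359	209.477611948442
B	520.992308806343	684.859122569151
3	528.320976647588	61.2112227300878
C	709.272947468112	241.893647041811
4	524.563036471033	550.560664772505
D	706.028718758692	65.1480976046055
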
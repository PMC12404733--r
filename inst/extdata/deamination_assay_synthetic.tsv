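enzyme	concentration	G	A
WT	0.125	550	450
WT	0.25	700	300
WT	0.5	850	150
WT	1	930	70
WT	2	960	40
V128M	0.125	176	824
V128M	0.25	310	690
V128M	0.5	520	480
V128M	1	700	300
V128M	2	820	180
A180V	0.125	540	460
A180V	0.25	690	310
A180V	0.5	845	155
A180V	1	925	75
A180V	2	955	45
A180L	0.125	132	868
A180L	0.25	240	760
A180L	0.5	430	570
A180L	1	610	390
A180L	2	760	240
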
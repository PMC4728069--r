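# Observed frequency ranges (Hz) per species / call type.
# Edit or extend freely; keys are matched exactly by species_bands().
key	low_hz	high_hz
brown_kiwi.male	500	8000
brown_kiwi.female	500	6500
ruru.trill	500	8000
ruru.more	500	2000
ruru.pork	500	2000
kakapo.booming	0	800
kakapo.chinging	1000	12000
ni_robin.song	1700	12500
tui.song	400	18000
ni_kaka.song	700	15000
hihi.song	1000	21000
ni_saddleback.song	800	22000
marsh_wren.song	500	15000
western_meadowlark.song	650	12500
horned_lark.song	1100	18000
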
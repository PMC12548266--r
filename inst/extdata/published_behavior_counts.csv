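behavior,HEC,GB,SLRE,BSR,ELS,ELE
annual_spring_river,30,17,0,3,0,29
intermittent_spring_river,80,35,5,3,24,22
intermittent_two_step,14,74,45,11,0,1
river_resident,33,8,44,1,0,0
annual_summer_river,42,30,0,0,4,3
annual_winter_river,17,21,0,0,0,0
annual_interlake,22,0,0,0,0,0
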
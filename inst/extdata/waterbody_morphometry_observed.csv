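scenario,shoreline_length_m,surface_area_m2,volume_m3
spring_before,38658,1929062,61222951
summer_before,33073,1413644,55537364
spring_after,8953,278267,12330116
summer_after,6882,163523,11469570
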
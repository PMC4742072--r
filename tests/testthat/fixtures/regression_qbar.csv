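"tag","nv","pb","pe","dtv","dtg","tr","f","qbar_ml_hr"
"baseline",4,9,2,0.5,0.5,1.5,0.5,1.14578676568144
"favorable_nv1",1,3,2,0.5,0.5,1.5,0.5,3.29149747392139
"adverse_pe3_nv2",2,16,3,0.5,0.5,1.5,0.5,0.388917746885241
"synchronous",4,6,2,0,0,1.5,0.5,1.6172152418753
"junction_only",4,9,2,0,0.5,1.5,0.5,1.533681678289
"short_diastole",4,3,2,0.5,0.5,0.5,0.5,1.13388770134552
"long_diastole_nv2",2,9,2,0.5,0.5,3.5,0.5,0.674139864438758
"half_cycle_delay",4,12,2,1.75,1.75,1.5,0.5,0.371878070267875
"collapse_pe5",2,9,5,0.5,0.5,1.5,0.5,0.0333178382502888
"fast_contraction",4,9,2,0.5,0.5,1.2,0.8,1.40944869547295
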
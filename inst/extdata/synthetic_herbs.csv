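quadrat_id,subquadrat_id,species,abundance,coverage_pct,height_m
3,1,Carex brunnea,7,17.0206335183193,0.142346618294202
4,1,Carex brunnea,5,17.0512593967217,0.0794531896755329
1,2,Carex brunnea,5,20.9178669199612,0.169462021015532
3,2,Carex brunnea,10,27.314351408304,0.345909679182259
4,2,Carex brunnea,3,13.3593037105276,0.143875071477033
1,3,Carex brunnea,6,18.3446256299668,0.118541815392614
2,3,Carex brunnea,12,16.9156700274388,0.222825799955004
3,3,Carex brunnea,9,22.2618065108528,0.1874564003259
4,3,Carex brunnea,10,10.7609263950361,0.277009723116324
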
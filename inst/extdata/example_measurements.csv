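bundle_id,cell_type,stereocilium_id,ref_stereocilium_id,row,kind,side,stage_tilt_deg,parallel_angle_deg,value_um
demo1,OHC,r1_01,,1,full_length,lateral,0.000000,10.000000,0.416760
demo1,OHC,r2_01,r1_01,2,step_1_to_2,medial,50.000000,10.000000,0.385680
demo1,OHC,r3_01,r1_01,3,step_1_to_3,medial,50.000000,10.000000,0.578790
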
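link_id,origin_region,origin_row,target_row,axis_sign,elevation_sign,expected_tip_link,note
L01,top_cap,2,1,1,1,TRUE,canonical tip link row 2 to row 1
L02,top_cap,3,1,1,1,TRUE,tip link skipping a row
L03,top_cap,3,2,1,1,TRUE,tip link row 3 to row 2
L04,top_cap,unranked,3,1,1,TRUE,supernumerary origin below row 3
L05,top_cap,2,2,0,0,FALSE,lateral link between row-2 neighbours
L06,top_cap,1,2,-1,-1,FALSE,origin taller than target
L07,top_cap,2,1,-1,1,FALSE,axis component away from taller rows
L08,top_cap,2,1,1,-1,FALSE,oblique downward
L09,tip_hemisphere_other,2,1,1,1,FALSE,origin on tip hemisphere but not top cap
L10,tip_hemisphere_other,3,2,-1,0,FALSE,hemisphere origin lateral
L11,shaft,2,1,1,1,FALSE,shaft origin
L12,shaft,3,3,0,1,FALSE,shaft origin same row
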
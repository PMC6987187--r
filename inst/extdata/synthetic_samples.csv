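sample_id,tissue,subset,group,replicate
cold_ck_leaf_r1,leaf,cold,ck,1
cold_4h_leaf_r1,leaf,cold,4h,1
cold_12h_leaf_r1,leaf,cold,12h,1
cold_ck_root_r1,root,cold,ck,1
cold_4h_root_r1,root,cold,4h,1
cold_12h_root_r1,root,cold,12h,1
cold_ck_leaf_r2,leaf,cold,ck,2
cold_4h_leaf_r2,leaf,cold,4h,2
cold_12h_leaf_r2,leaf,cold,12h,2
cold_ck_root_r2,root,cold,ck,2
cold_4h_root_r2,root,cold,4h,2
cold_12h_root_r2,root,cold,12h,2
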
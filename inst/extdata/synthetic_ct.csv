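gene,cold_ck_leaf_r1,cold_4h_leaf_r1,cold_12h_leaf_r1,cold_ck_root_r1,cold_4h_root_r1,cold_12h_root_r1,cold_ck_leaf_r2,cold_4h_leaf_r2,cold_12h_leaf_r2,cold_ck_root_r2,cold_4h_root_r2,cold_12h_root_r2
g01,20.238,20.108,19.815,19.950,20.185,20.281,20.027,19.874,19.812,19.792,19.718,20.083
g02,22.236,21.939,21.967,22.026,22.026,22.248,21.963,21.942,21.704,21.896,21.616,22.133
g03,24.264,23.996,23.864,24.043,24.057,24.258,24.206,24.369,23.516,23.802,23.731,24.227
g04,26.388,26.676,25.812,25.728,26.038,25.950,25.903,25.545,26.024,25.704,25.966,26.084
g05,28.993,28.524,28.248,28.045,29.055,28.194,27.109,28.332,28.001,26.716,28.231,27.490
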
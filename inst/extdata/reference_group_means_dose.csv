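structure,metric,mean_A,sd_A,mean_B,sd_B,mean_C,sd_C,p_A-B,p_A-C,p_B-C
PTV,D_0.03cc,7624.9,74.6,7648,103.19,7607.7,44.12,0.097,0.246,0.216
PTV,CN,0.85,0.04,0.86,0.04,0.86,0.04,0.019,0.003,0.348
PTV,HI,0.06,0.01,0.06,0.01,0.06,0.01,0.246,0.313,0.348
PTV,GI,3.03,0.56,2.93,0.46,2.83,0.48,0.097,0.002,0.042
spinal_cord,D_0.03cc,2365.1,591.9,2104.4,504.1,1750.2,489.9,0.080,0.001,0.002
spinal_cord,D_mean,1406.7,441.8,1296.0,386.9,1086.6,405.7,0.161,0.001,0.001
brain_stem,D_0.03cc,1618.4,1633.0,1581.1,1676.1,1281.1,1185.6,0.216,0.002,0.005
brain_stem,D_mean,626.1,782.2,658.5,864.7,520.4,588.2,0.246,0.007,0.001
parotid_L,D_0.03cc,7143.8,579.2,7162.4,478.3,7128.6,623.9,0.461,0.385,0.423
parotid_L,D_mean,2629.1,1070.9,2525.1,1174.4,2170.9,977.2,0.246,0.001,0.002
parotid_R,D_0.03cc,7122.1,695.1,7084.9,686.2,7102.9,674.7,0.053,0.188,0.216
parotid_R,D_mean,3211.7,1472.8,3088.7,1527.2,2787.2,1464.1,0.313,0.001,0.002
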
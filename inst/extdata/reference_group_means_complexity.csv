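metric,mean_A,sd_A,mean_B,sd_B,mean_C,sd_C,p_A-B,p_A-C,p_B-C
MCSv,0.17,0.08,0.09,0.01,0.1,0.03,0.007,0.010,0.161
MU,1268.2,225.9,1309.7,223.2,1240.6,157.2,0.216,0.313,0.138
PA,32.0,6.2,29.9,4.1,31.4,8.2,0.042,0.385,0.138
PI,200.2,67.2,265.13,112.0,284.2,66.5,0.005,0.001,0.385
PM,0.86,0.02,0.87,0.02,0.87,0.02,0.065,0.461,0.188
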
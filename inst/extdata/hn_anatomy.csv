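patient,site,ptv_cc,cord_cc,brainstem_cc,parotid_l_cc,parotid_r_cc,cord_dist_cm,brainstem_dist_cm,parotid_l_dist_cm,parotid_r_dist_cm
1,Hypopharynx & Neck,697.19,40.56,23.91,14.50,12.87,5.64,13.88,11.96,9.94
2,Hypopharynx,418.36,28.50,26.28,24.01,23.86,5.33,13.59,10.26,10.53
3,Nasopharynx,771.38,30.38,24.69,43.90,38.94,8.38,10.29,8.54,8.35
4,Nasopharynx,578.28,29.76,24.6,26.21,23.85,6.88,10.55,8.19,8.65
5,Oropharynx & Neck,541.35,20.10,24.17,25.45,24.54,7.26,9.79,6.95,7.87
6,Hypopharynx & Neck,691.96,38.66,25.01,18.20,17.86,7.04,13.09,11.09,9.65
7,Nasopharynx & Neck,706.52,42.03,31.17,50.85,53.08,9.36,10.08,8.77,8.78
8,Larynx & Neck,373.81,21.82,24.98,43.07,37.00,5.72,10.80,8.10,8.42
9,Larynx & Neck,323.48,31.52,30.30,25.69,28.51,6.65,12.51,9.84,10.04
10,Hypopharynx & Neck,716.45,30.68,23.89,22.13,27.03,5.82,12.10,10.11,9.16
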
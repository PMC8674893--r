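lineage,site,n_rapture,Ho,He,G_IS,prop_poly_rapture,ne,ne_ci_low,ne_ci_high,af_del,prop_del,n_mhc,n_hap,prop_poly_mhc,prop_gt2
MS,LHY,26,0.236,0.273,0.136,0.917,561,504,631,0.72,1,25,7.96,0.96,0.24
MS,SGR,23,0.125,0.173,0.276,0.781,36,35,37,0.71,0.97,18,7.43,0.78,0.50
MS,LNG,18,0.177,0.254,0.302,0.866,437,362,552,0.73,1,11,6.41,0.82,0.36
MS,BEA,30,0.130,0.178,0.267,0.783,519,456,602,0.70,0.93,26,5.45,0.69,0.46
MS,GRD,28,0.170,0.224,0.244,0.854,207,198,217,0.70,0.97,27,5.37,0.78,0.33
MS,ATK,54,0.103,0.125,0.173,0.706,128,124,132,0.74,0.89,41,2.95,0.90,0.34
MS,TRU,30,0.257,0.264,0.028,0.897,131,128,134,0.71,0.99,5,8.00,0.80,0.40
MS,PIK,30,0.185,0.216,0.142,0.826,584,521,665,0.73,0.96,21,2.68,0.48,0
MS,PRS,30,0.178,0.245,0.273,0.880,155,151,161,0.73,0.98,27,5.25,0.67,0.33
MS,TRT,13,0.174,0.243,0.286,0.851,231,201,271,0.71,0.97,15,8.29,1.00,0.47
MS,WSL,30,0.228,0.237,0.039,0.868,1781,1355,2593,0.70,0.97,28,5.64,0.79,0.39
MS,MSK,29,0.154,0.209,0.263,0.819,157,151,164,0.73,0.95,24,4.36,0.83,0
MS,PLT,30,0.176,0.192,0.084,0.809,798,678,970,0.73,0.95,28,3.27,0.61,0
MS,PLM,30,0.211,0.221,0.046,0.845,636,567,726,0.74,0.96,26,5.91,0.73,0.15
MS,TOM,30,0.215,0.257,0.163,0.902,532,486,587,0.74,0.98,26,8.28,0.96,0.38
MS,TWS,30,0.202,0.219,0.079,0.849,261,248,275,0.74,0.98,29,5.37,0.90,0.38
MS,BLK,24,0.127,0.190,0.330,0.794,63,62,65,0.74,0.94,14,4.29,0.64,0
MS,LGL,28,0.136,0.233,0.415,0.864,821,684,1025,0.74,0.98,29,7.15,0.90,0.28
MS,SVN,29,0.162,0.185,0.125,0.798,385,353,423,0.73,0.92,27,3.69,0.85,0
GL,RBW,19,0.211,0.234,0.101,0.851,1327,940,2256,0.70,0.96,18,5.02,0.78,0.06
GL,SPN,30,0.183,0.213,0.142,0.840,296,279,316,0.70,0.96,17,6.09,0.88,0.35
GL,GIL,28,0.185,0.230,0.198,0.840,147,142,152,0.72,0.98,26,6.76,0.81,0.38
GL,GRN,29,0.190,0.262,0.274,0.916,274,259,290,0.70,1,18,6.63,0.94,0.50
GL,ELK,20,0.139,0.256,0.460,0.871,282,255,316,0.71,0.96,18,6.38,0.83,0.28
GL,OKA,28,0.103,0.218,0.525,0.834,355,317,402,0.68,0.92,27,6.01,0.93,0.07
GL,GNV,30,0.147,0.207,0.289,0.845,391,358,431,0.67,0.98,27,9.15,0.96,0.33
GL,HOW,15,0.146,0.163,0.103,0.733,Inf,Inf,Inf,0.68,0.87,13,6.50,0.92,0.15
GL,EVE,7,0.057,0.136,0.582,0.646,Inf,Inf,Inf,0.66,0.80,7,6.13,0.86,0.57
GL,CRD,22,0.164,0.192,0.145,0.800,47,46,48,0.67,0.91,11,5.52,0.91,0.45
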
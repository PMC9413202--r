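compound,central_pbpk,central_lumped,central_compartment,peripheral_pbpk,peripheral_lumped,peripheral_compartment,cl_pbpk,cl_lumped,cl_compartment
Alfentanil,0.348,0.351,0.585,1.772,0.994,NA,0.555,0.555,0.209
Amlodipine,7.598,0.505,0.496,9.979,11.920,NA,0.408,0.408,0.255
Artemether,2.608,2.877,0.173,27.217,19.090,NA,13.333,13.333,16.436
Caffeine,1.349,1.482,0.953,0.901,0.638,NA,0.134,0.134,0.094
Clozapine,130.033,12.823,14.172,142.308,134.485,NA,0.401,0.401,0.313
Cyclosporine A,21.776,12.285,18.363,17.777,12.601,NA,0.420,0.420,0.459
Digoxin,0.056,0.060,0.030,0.077,0.057,0.030,0.136,0.136,0.222
Fluoxetine,2.736,1.926,4.511,20.178,13.400,NA,0.351,0.351,0.208
Metoprolol,0.987,1.074,0.630,5.476,2.644,NA,3.250,3.250,2.821
Midazolam,1.005,0.977,0.098,8.860,5.189,0.100,0.540,0.540,0.896
Nevirapine,146.303,164.225,203.575,315.957,208.837,202.734,0.022,0.022,0.015
Ofloxacin,50.220,53.246,55.173,34.537,29.840,55.224,0.160,0.160,0.132
Paracetamol,28.650,33.827,67.964,18.966,19.120,68.139,0.270,0.270,0.215
Pioglitazone,2.368,3.201,5.529,0.348,0.312,3.002,0.068,0.068,0.035
Rifampicin,153.468,79.553,65.084,139.803,163.653,NA,0.142,0.142,0.163
S-Warfarin,28.075,35.292,30.006,6.697,5.905,NA,0.003,0.003,0.002
Telmisartan,760.097,986.822,0.707,164.733,123.565,0.694,0.800,0.800,0.980
Theophylline,468.329,554.051,65.239,291.616,279.114,NA,0.045,0.045,0.054
Thiopental,1688.083,1819.869,3015.313,11940.270,7818.454,2773.715,0.189,0.189,0.114
Voriconazole,43.587,46.360,63.400,260.225,273.008,63.054,0.106,0.106,0.088
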
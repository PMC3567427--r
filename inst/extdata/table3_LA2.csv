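substrate_id,role,Molecular_Weight,CHI_0,Dipole_Y,Shadow_XYfrac,Jurs_FPSA_1,observed_log,published_pred,published_residual
1,training,176.212,9.519,0.059,0.623,0.677,1.161,1.158,0.003
3,training,885.432,45.786,0.001,0.263,0.896,0.973,0.98,-0.007
4,training,358.556,18.59,0.135,0.645,0.882,1.288,1.311,-0.023
5,training,975.639,50.029,-0.166,0.185,0.94,1.403,1.396,0.007
7,training,214.344,11.356,0.917,0.69,0.901,1.107,1.107,0.005
8,training,256.424,13.477,0.943,0.677,0.912,0.973,0.995,-0.022
9,training,270.451,14.184,0.199,0.696,0.918,1.236,1.205,0.031
10,training,294.472,15.598,0.054,0.438,0.865,1.215,1.207,0.008
12,training,242.397,12.77,0.223,0.584,0.91,1.344,1.367,-0.023
13,training,284.477,14.891,0.949,0.677,0.919,1.013,1.002,0.011
14,training,310.515,16.305,1.094,0.44,0.901,1.068,1.074,-0.006
15,training,312.53,16.305,0.934,0.534,0.926,1.236,1.215,0.021
2,test,322.525,15.525,1.153,0.251,1.332,1.121,1.084,0.037
6,test,807.32,38.64,-0.077,0.669,0.911,1.427,1.127,0.300
11,test,184.146,6.813,1.384,0.394,1.392,1.155,1.058,0.097
16,test,298.504,14.63,0.905,0.696,3.655,1.121,1.191,-0.07
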
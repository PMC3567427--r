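substrate_id,role,ALogP_MR,Molecular_Volume,Molecular_PolarSASA,Shadow_XYfrac,Jurs_PPSA_3,observed_log,published_pred,published_residual
1,training,51.297,122.79,49.521,0.623,17.109,1.097,1.084,0.013
3,training,296.502,793.01,115.261,0.185,58.06,1.389,1.388,0.001
4,training,77.398,204.42,49.521,0.677,18.406,0.875,0.902,-0.027
5,training,72.65,194.13,49.521,0.584,18.693,1.283,1.244,0.039
7,training,272.246,710.35,115.261,0.263,55.106,0.875,0.871,0.004
8,training,93.287,229.8,49.521,0.438,23.066,1.09,1.092,-0.002
9,training,103.309,283.66,120.524,0.645,32.625,1.336,1.341,-0.005
10,training,95.802,251.41,49.521,0.534,21.828,1.124,1.131,-0.007
12,training,96.919,247.3,49.521,0.44,22.368,1.033,1.057,-0.024
13,training,63.448,169.09,49.521,0.69,16.925,1.049,1.041,0.008
14,training,81.852,218.14,49.521,0.696,20.233,1.199,1.228,-0.029
15,training,86.6,227.4,49.521,0.677,19.962,0.959,0.923,0.036
2,test,91.054,239.07,49.521,0.696,21.797,1.158,1.084,0.074
6,test,102.636,253.81,49.521,0.64,23.527,1.452,1.127,0.325
11,test,241.29,651.35,115.261,0.394,48.528,1.097,1.058,0.039
16,test,42.667,111.47,156.026,0.251,27.008,0.987,1.191,-0.204
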
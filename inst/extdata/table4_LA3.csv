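substrate_id,role,CHI_1,Dipole_X,Jurs_FNSA_3,Jurs_FPSA_3,Shadow_XY,observed_log,published_pred,published_residual
1,training,6.326,0.67,-0.042,0.041,62.211,1.025,1.028,-0.003
3,training,31.028,1.397,-0.019,0.029,280.042,1.053,1.051,0.002
4,training,12.202,1.297,-0.037,0.04,127.108,1.243,1.239,0.004
5,training,34.028,0.379,-0.013,0.028,342.582,1.334,1.337,-0.003
7,training,7.308,-0.244,-0.024,0.031,75.615,1.021,1.037,-0.016
8,training,8.808,-0.173,-0.018,0.029,90.705,1.053,1.012,0.041
9,training,9.308,0.926,-0.02,0.03,95.404,1.212,1.218,-0.006
10,training,10.308,0.67,-0.023,0.033,109.456,1.152,1.146,0.006
12,training,8.308,0.898,-0.021,0.031,86.059,1.199,1.202,-0.003
13,training,9.808,-0.171,-0.016,0.028,100.225,0.929,0.948,-0.019
14,training,10.808,-0.019,-0.017,0.029,113.043,1.017,1.011,0.006
15,training,10.808,0.109,-0.015,0.028,111.62,1.004,1.015,-0.011
2,test,19.308,1.67,-0.052,0.032,105.063,1.053,1.084,-0.0309
6,test,7.308,0.898,-0.089,0.055,261.979,1.439,1.127,0.3123
11,test,9.608,-0.271,-0.096,0.092,119.779,1.124,1.058,0.0658
16,test,11.808,-0.119,-0.019,0.011,57.29,1.127,1.191,-0.0639
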
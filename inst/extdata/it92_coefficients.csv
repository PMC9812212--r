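element,a1,a2,a3,a4,b1,b2,b3,b4,c
H,0.493002,0.322912,0.140191,0.04081,10.5109,26.1257,3.14236,57.7997,0.003038
C,2.31,1.02,1.5886,0.865,20.8439,10.2075,0.5687,51.6512,0.2156
N,12.2126,3.1322,2.0125,1.1663,0.0057,9.8933,28.9975,0.5826,-11.529
O,3.0485,2.2868,1.5463,0.867,13.2771,5.7011,0.3239,32.9089,0.2508
NA,4.7626,3.1736,1.2674,1.1128,3.285,8.8422,0.3136,129.424,0.676
MG,5.4204,2.1735,1.2269,2.3073,2.8275,79.2611,0.3808,7.1937,0.8584
P,6.4345,4.1791,1.78,1.4908,1.9067,27.157,0.526,68.1645,1.1149
S,6.9053,5.2034,1.4379,1.5863,1.4679,22.2151,0.2536,56.172,0.8669
CL,11.4604,7.1964,6.2556,1.6455,0.0104,1.1662,18.5194,47.7784,-9.5574
CL1-,18.2915,7.2084,6.5337,2.3386,0.0066,1.1717,19.5424,60.4486,-16.378
K,8.2186,7.4398,1.0519,0.8659,12.7949,0.7748,213.187,41.6841,1.4228
CA,8.6266,7.3873,1.5899,1.0211,10.4421,0.6599,85.7484,178.437,1.3751
FE,11.7695,7.3573,3.5222,2.3045,4.7611,0.3072,15.3535,76.8805,1.0369
ZN,14.0743,7.0318,5.1652,2.41,3.2655,0.2333,10.3163,58.7097,1.3041
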
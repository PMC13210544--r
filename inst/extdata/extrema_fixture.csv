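crop,code,month,ndvi_min,ndvi_max,sr_min,sr_max
maize,1,6,0.327,0.735,1.972,6.547
maize,1,7,0.834,0.917,11.048,23.096
maize,1,8,0.831,0.852,10.834,12.514
maize,1,9,0.675,0.791,5.154,8.569
maize,1,10,0.200,0.221,1.500,1.567
rice,2,6,0.417,0.653,2.431,4.764
rice,2,7,0.714,0.881,5.993,15.807
rice,2,8,0.740,0.831,6.692,10.834
rice,2,9,0.560,0.656,3.545,4.814
rice,2,10,0.427,0.489,2.490,2.914
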
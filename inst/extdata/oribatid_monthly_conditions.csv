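"month","temp_mean","temp_sd","rh_mean","rh_sd","h2_prime","dprime_dead_wood","dprime_litter","dprime_moss"
1,2.1,1.4,79,16,0.35,0.39,0.36,0.3
2,7.4,2.8,92,12,0.4,0.32,0.49,0.41
3,3.6,1,100,17,0.24,0.22,0.38,0.15
4,11.1,3.2,88,19,0.19,0.17,0.31,0.08
5,12.1,3.3,58,21,0.36,0.26,0.54,0.28
6,16.7,1.2,99,10,0.23,0.23,0.33,0.16
7,17,1.4,94,9,0.1,0.1,0.16,0.07
8,16,2.8,93,12,0.19,0.18,0.27,0.14
9,18.1,1.3,89,12,0.22,0.14,0.41,0.13
10,13.1,1.9,97,10,0.25,0.3,0.23,0.19
11,5.1,1.3,100,7,0.32,0.35,0.34,0.27
12,0.4,2.4,97,10,0.49,0.51,0.42,0.51
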
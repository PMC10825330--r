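response,temperature_C,k,k_sd,Cs,Cs_sd,R2,chisq,RMSE
YP,30,0.00556,0.00011,16.536,0.101,0.944,0.081,0.285
YP,40,0.00597,0.00007,17.976,0.055,0.976,0.010,0.101
YP,50,0.00607,0.00004,20.968,0.045,0.955,0.007,0.083
YP,60,0.00702,0.00019,22.136,0.154,0.978,0.028,0.166
YA,30,0.00233,0.00008,74.006,0.691,0.986,0.006,0.076
YA,40,0.00332,0.00019,75.740,0.998,0.979,0.003,0.059
YA,50,0.00479,0.00013,76.519,0.347,0.963,0.006,0.077
YA,60,0.00564,0.00018,81.462,0.432,0.959,0.003,0.053
YB,30,0.00439,0.00014,45.816,0.344,0.961,0.013,0.113
YB,40,0.00497,0.00010,51.325,0.242,0.983,0.025,0.158
YB,50,0.00603,0.00029,54.314,0.496,0.972,0.790,0.889
YB,60,0.00678,0.00036,60.749,0.483,0.965,0.016,0.128
YF,30,0.07007,0.00333,1.560,0.022,0.948,0.007,0.083
YF,40,0.09518,0.00651,1.790,0.028,0.975,0.004,0.059
YF,50,0.09824,0.00525,2.058,0.027,0.959,0.019,0.136
YF,60,0.11215,0.00471,2.350,0.021,0.990,0.007,0.085
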
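response,temperature_C,De_m2_s,Kt_m_s
YP,30,1.433e-11,1.330e-06
YP,40,1.748e-11,1.467e-06
YP,50,2.111e-11,1.621e-06
YP,60,2.555e-11,1.816e-06
YA,30,2.830e-11,1.935e-06
YA,40,3.766e-11,2.341e-06
YA,50,4.760e-11,2.771e-06
YA,60,5.362e-11,3.032e-06
YB,30,3.187e-11,2.087e-06
YB,40,3.766e-11,2.338e-06
YB,50,4.497e-11,2.655e-06
YB,60,5.093e-11,2.916e-06
YF,30,1.766e-11,1.472e-06
YF,40,2.783e-11,1.915e-06
YF,50,3.158e-11,2.077e-06
YF,60,3.912e-11,2.404e-06
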
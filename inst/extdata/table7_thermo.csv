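response,temperature_C,Bi,dH_kJ_mol,dS_J_mol_K,dG_kJ_mol
YP,30,14.111,51.975,177.321,-1.753
YP,40,12.752,51.975,177.321,-3.526
YP,50,11.674,51.975,177.321,-5.300
YP,60,10.804,51.975,177.321,-7.073
YA,30,10.395,28.083,106.943,-4.321
YA,40,9.448,28.083,106.943,-5.390
YA,50,8.850,28.083,106.943,-6.460
YA,60,8.596,28.083,106.943,-7.529
YB,30,9.956,66.896,227.280,-1.970
YB,40,9.438,66.896,227.280,-4.242
YB,50,8.974,66.896,227.280,-6.515
YB,60,8.702,66.896,227.280,-8.788
YF,30,12.669,44.486,148.646,-0.554
YF,40,10.459,44.486,148.646,-2.040
YF,50,9.999,44.486,148.646,-3.527
YF,60,9.341,44.486,148.646,-5.013
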
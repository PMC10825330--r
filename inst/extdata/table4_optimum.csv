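response,experimental,experimental_sd,predicted,relative_deviation_pct
YP,16.698,0.142,17.860,6.960
YA,69.039,0.994,70.643,2.323
YB,49.947,0.889,54.281,8.678
YF,1.817,0.032,1.962,7.988
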
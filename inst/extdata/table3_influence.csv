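notation,dYP,dYA,dYB,dYF
XP,0.412,0.619,0.425,0.968
XT,-0.319,0.504,-0.176,-0.581
XS,-0.249,-0.203,0.253,-0.284
XC,-0.032,0.327,-0.244,0.395
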
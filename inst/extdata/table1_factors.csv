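name,notation,low,center,high
ultrasonic_power_W,XP,150,250,350
temperature_C,XT,30,50,70
solvent_to_solid_ratio_ml_g,XS,15,25,35
ethanol_concentration_pct,XC,40,60,80
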
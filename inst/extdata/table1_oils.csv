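oil,fatty_acid,mass_fraction_pct,mass_fraction_sd_pct
Soybean oil,palmitic,11.0,0.8
Soybean oil,stearic,4.5,0.4
Soybean oil,oleic,20.7,1.0
Soybean oil,linolenic,8.9,1.8
Soybean oil,linoleic,54.2,2.4
Olive oil,palmitic,14.5,1.3
Olive oil,stearic,2.5,1.2
Olive oil,oleic,70.0,1.0
Olive oil,linolenic,1.5,0.5
Olive oil,linoleic,12.0,1.0
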
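name	MW_kDa	Ve_mL
ferritin	440	8.71
aldolase	158	11.2
conalbumin	75	13.01
ovalbumin	44	14.31
carbonic_anhydrase	29	15.33
ribonuclease_A	13.7	17.15
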
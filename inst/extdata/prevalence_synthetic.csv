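condition,age_lo,age_hi,rate
hypertension,18,49,0.20
hypertension,50,75,0.60
hypertension,76,85,0.75
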
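segment,age_lo,age_hi,enrollment
Medicare,18,49,3451844
Medicare,50,75,32764347
Medicare,76,85,24783808
Medicaid,18,49,58514811
Medicaid,50,75,14485188
Medicaid,76,85,2000000
Marketplace,18,49,10250520
Marketplace,50,75,4352760
Marketplace,76,85,196720
Commercial,18,49,120098932
Commercial,50,75,39224431
Commercial,76,85,9676640
CA-Marketplace,18,49,850000
CA-Marketplace,50,75,642000
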
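period,scenario,non_suitable,low,moderate,high
Current,Current,10894427,471397,360939,1200282
2050s,SSP1-2.6,11386961,345528,465098,719241
2050s,SSP2-4.5,11432190,343446,375633,765558
2050s,SSP3-7.0,11528263,343727,467651,577186
2050s,SSP5-8.5,11500569,376849,366425,672985
2100s,SSP1-2.6,11566635,337221,388768,624203
2100s,SSP2-4.5,11847665,412899,371439,284824
2100s,SSP3-7.0,12213550,417520,218893,66865
2100s,SSP5-8.5,11927266,538183,265671,185707
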
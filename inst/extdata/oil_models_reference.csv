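# Reported grouped multiple-regression models y = b1*X1 + b2*X2 + b0 (y = shelf-life in days,
# X1 = saturation-class predictor, X2 = binary group indicator) over the nine non-pumpkin oils,
# with reported multiple correlation coefficients and overall p-values.
predictor,response,b1,b2,b0,multiple_r,p_value
sfa,20,142,600,-1474,0.8374,0.0266
sfa,25,90,378,-935,0.8291,0.0306
ufa,20,-138,550,12337,0.8953,0.0078
ufa,25,-88,347,7868,0.8885,0.0093
sfa_ufa_ratio,20,10563,586,-1224,0.8376,0.0266
sfa_ufa_ratio,25,6717,370,-776,0.8292,0.0305
pufa,20,-14,512,773,0.7615,0.0741
pufa,25,-9,326,500,0.7666,0.0701
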
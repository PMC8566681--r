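# Reference physicochemical properties of the ten expeller-pressed seed oils.
# sfa/ufa/pufa: printed saturation-class sums (% of FAMEs); iodine_value: calculated, g I2/100 g oil;
# smoke_point: degC; acid_value: mg KOH/g oil; group_x2: binary indicator used by the grouped
# shelf-life regression (0 or 1 per the two-curve grouping; NA for the excluded pumpkin seed oil);
# excluded: oil left out of the correlation/regression screens.
oil_id,sfa,ufa,pufa,iodine_value,smoke_point,acid_value,group_x2,excluded
Almond oil,9.55,90.44,26.64,101.1,174.8,0.53,0,FALSE
Black sesame oil,17.43,82.58,44.33,109.7,172.8,3.89,0,FALSE
Camellia oil,12.39,87.60,8.79,83.0,176.5,1.37,0,FALSE
Golden linseed oil,8.85,91.16,69.66,187.2,134.3,1.70,1,FALSE
Peanut oil,14.43,84.06,4.91,76.6,141.8,1.06,1,FALSE
Pecan oil,10.70,89.30,31.11,103.9,193.7,0.23,1,FALSE
Pine nut oil,9.27,90.73,61.22,145.5,165.8,1.51,1,FALSE
Pumpkin seed oil,20.32,79.67,47.58,110.3,184.3,2.27,NA,TRUE
Sunflower seed oil,11.00,88.99,52.17,122.2,109.0,1.85,0,FALSE
Walnut oil,8.91,91.10,76.34,159.4,148.3,2.26,1,FALSE
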
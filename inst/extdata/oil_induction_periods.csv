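# Induction periods (h) of the ten expeller-pressed seed oils measured at 70, 90 and 100 degC
# under 800 kPa oxygen, 5 g sample. censored = TRUE marks an induction period beyond the 240 h
# instrumental upper limit (ip_hours empty).
oil_id,temperature_C,ip_hours,censored
Almond oil,70,85.00,FALSE
Almond oil,90,20.62,FALSE
Almond oil,100,8.83,FALSE
Black sesame oil,70,144.00,FALSE
Black sesame oil,90,21.92,FALSE
Black sesame oil,100,8.78,FALSE
Camellia oil,70,85.22,FALSE
Camellia oil,90,14.20,FALSE
Camellia oil,100,6.63,FALSE
Golden linseed oil,70,34.48,FALSE
Golden linseed oil,90,4.60,FALSE
Golden linseed oil,100,1.78,FALSE
Peanut oil,70,,TRUE
Peanut oil,90,81.52,FALSE
Peanut oil,100,33.62,FALSE
Pecan oil,70,151.00,FALSE
Pecan oil,90,25.08,FALSE
Pecan oil,100,10.11,FALSE
Pine nut oil,70,74.00,FALSE
Pine nut oil,90,10.88,FALSE
Pine nut oil,100,4.32,FALSE
Pumpkin seed oil,70,145.00,FALSE
Pumpkin seed oil,90,23.05,FALSE
Pumpkin seed oil,100,9.55,FALSE
Sunflower seed oil,70,62.60,FALSE
Sunflower seed oil,90,10.32,FALSE
Sunflower seed oil,100,4.62,FALSE
Walnut oil,70,44.47,FALSE
Walnut oil,90,6.50,FALSE
Walnut oil,100,2.67,FALSE
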
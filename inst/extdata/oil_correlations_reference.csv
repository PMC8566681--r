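# Reported Pearson correlations between oil properties and shelf-lives at 20 and 25 degC over
# the nine non-pumpkin oils. significant: reported p < 0.05 flag.
variable,r_20,r_25,significant
log_ip_70,0.9094,0.9124,TRUE
log_ip_90,0.8394,0.8451,TRUE
log_ip_100,0.8177,0.8242,TRUE
smoke_point,-0.0197,-0.0192,FALSE
acid_value,-0.0890,-0.0995,FALSE
iodine_value,-0.5222,-0.5320,FALSE
sfa,0.5910,0.5881,FALSE
ufa,-0.6972,-0.6951,TRUE
pufa,-0.5549,-0.5654,FALSE
sfa_ufa_ratio,0.6006,0.5975,FALSE
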
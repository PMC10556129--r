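source,fatty_acid,delta_mean,delta_sd,conc_pct_fa,fa_per_dry_weight
maize,C16:0,-14.5,1.0,12,0.045
maize,C18:0,-16.0,1.0,2,0.045
maize,C18:1,-13.5,1.0,30,0.045
marine,C16:0,-24.0,1.5,18,0.25
marine,C18:0,-23.0,1.5,6,0.25
marine,C18:1,-23.5,1.5,20,0.25
C3_plant,C16:0,-30.5,1.2,15,0.10
C3_plant,C18:0,-31.5,1.2,3,0.10
C3_plant,C18:1,-30.0,1.2,35,0.10
ruminant,C16:0,-29.0,1.0,25,0.60
ruminant,C18:0,-31.0,1.0,20,0.60
ruminant,C18:1,-29.5,1.0,30,0.60
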
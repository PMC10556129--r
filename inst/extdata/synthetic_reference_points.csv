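class,d13c_16_0,d13c_18_0
marine,-25.26,-23.16
marine,-23.96,-21.9
marine,-24.03,-22.52
marine,-22.18,-21.75
marine,-24.6,-24.5
marine,-22.78,-21.33
marine,-22.82,-23.13
marine,-25.28,-23.37
marine,-24.87,-24.35
marine,-23.11,-22.52
marine,-24.5,-23.73
marine,-24.88,-23.38
estuarine,-25.7,-24.26
estuarine,-25.49,-24.56
estuarine,-25.08,-22.67
estuarine,-26.33,-24.81
estuarine,-26.64,-25.01
estuarine,-26.2,-25.04
estuarine,-26.03,-25.96
estuarine,-24.76,-25.6
estuarine,-25.43,-25.04
estuarine,-25.68,-24.15
estuarine,-25.46,-24.54
estuarine,-25.31,-24.98
freshwater,-28.53,-28.47
freshwater,-27.59,-26.69
freshwater,-28.48,-27.2
freshwater,-27.32,-26.26
freshwater,-28.43,-28.57
freshwater,-26.62,-25.69
freshwater,-27.63,-25.77
freshwater,-28.15,-27.63
freshwater,-28.18,-27.93
freshwater,-28.8,-27.78
freshwater,-28.17,-27.92
freshwater,-29.27,-28.37
ruminant,-29.69,-32.16
ruminant,-29.81,-31.11
ruminant,-27.26,-30.96
ruminant,-28.01,-29.96
ruminant,-28.55,-30.18
ruminant,-28.12,-30.79
ruminant,-29.43,-30.29
ruminant,-27.84,-29.97
ruminant,-29.27,-29.7
ruminant,-28.21,-30.95
ruminant,-27.29,-29.25
ruminant,-30.55,-32.46
C3_plant,-29.59,-31.55
C3_plant,-31.6,-31.76
C3_plant,-30.89,-32.33
C3_plant,-30.55,-31.95
C3_plant,-30.71,-33.49
C3_plant,-31.22,-32.65
C3_plant,-30.4,-30.54
C3_plant,-28.98,-32.03
C3_plant,-30.04,-32.82
C3_plant,-31.7,-32.24
C3_plant,-29.86,-31.86
C3_plant,-31.35,-31.79
maize,-13.85,-15.86
maize,-13.29,-15.69
maize,-14.72,-16.04
maize,-14.77,-15.57
maize,-13.54,-15.33
maize,-15,-16.95
maize,-15.03,-15.67
maize,-14.91,-15.96
maize,-14.76,-15.46
maize,-13.69,-15.65
maize,-15.47,-16.5
maize,-14.57,-16.17
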
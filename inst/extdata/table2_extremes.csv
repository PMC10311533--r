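solvent,calc_max_ppm,calc_min_ppm
D2O,62.1,-91.7
MeOD,98.2,-79.2
d6-DMSO,103.2,-150.0
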
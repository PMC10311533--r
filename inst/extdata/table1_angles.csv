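solvent,min_deg,max_deg,mean_deg,mean_prev_deg
D2O,40.1,64.1,51.8,52.0
MeOD,40.0,69.6,53.6,53.3
d6-DMSO,34.5,69.8,52.5,53.8
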
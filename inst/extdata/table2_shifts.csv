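solvent,proton,experimental_ppm,time_avg_ppm,avg_struct_ppm
D2O,H1,2.9,-1.4,44.1
D2O,H2,2.4,-1.9,30.4
D2O,H3,1.7,-3.2,119.5
MeOD,H1,16.2,16.0,37.1
MeOD,H2,13.6,13.5,19.4
MeOD,H3,16.6,17.5,26.9
d6-DMSO,H1,21.6,4.1,59.6
d6-DMSO,H2,18.0,3.6,-25.3
d6-DMSO,H3,22.3,4.9,-94.5
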
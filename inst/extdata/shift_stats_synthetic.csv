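residue_type,ss_class,mean_ca,sd_ca,mean_cb,sd_cb
THR,helix,65.5,1.2,68.5,1.0
THR,sheet,60.9,1.3,71.3,1.5
THR,coil,62.0,1.1,69.8,1.0
SER,helix,61.0,1.0,62.9,0.8
SER,sheet,56.9,1.2,65.3,1.3
SER,coil,58.3,1.0,63.9,0.9
GLY,helix,46.9,1.0,NA,NA
GLY,sheet,44.7,1.2,NA,NA
GLY,coil,45.4,1.0,NA,NA
ALA,helix,54.8,1.0,18.2,1.0
ALA,sheet,50.6,1.2,21.0,1.6
ALA,coil,52.5,1.0,19.0,1.1
VAL,helix,66.0,1.2,31.5,1.0
VAL,sheet,61.2,1.4,33.9,1.5
VAL,coil,62.3,1.1,32.6,1.0
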
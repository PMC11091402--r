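scheme,family,printed_mean
HPA,Molecular typing,99.8
KIR,Molecular typing,99.5
LOW,Molecular typing,99.4
B57,Molecular typing,99.4
HI,Molecular typing,99.0
B27,Molecular typing,99.0
CD,Molecular typing,98.3
AHPA,Antibodies,99.4
ALO,Antibodies,99.0
SER,Serology,98.9
XM,Crossmatch,97.7
XMFC,Crossmatch,95.6
CHM,Chimerism,94.8
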
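scheme,total
ALO,1464125
LOW,62848
HI,59082
XM,26873
KIR,26011
XMFC,12479
CD,11848
SER,9000
B57,8604
B27,5026
HPA,3518
CHM,2372
AHPA,720
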
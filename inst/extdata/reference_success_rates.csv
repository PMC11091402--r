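scheme,family,year,rate
HPA,Molecular typing,2017,100.0
HPA,Molecular typing,2018,100.0
HPA,Molecular typing,2019,99.0
HPA,Molecular typing,2020,99.5
HPA,Molecular typing,2021,100.0
HPA,Molecular typing,2022,100.0
KIR,Molecular typing,2016,98.9
KIR,Molecular typing,2017,99.4
KIR,Molecular typing,2018,99.3
KIR,Molecular typing,2019,99.7
KIR,Molecular typing,2020,99.8
KIR,Molecular typing,2021,99.7
KIR,Molecular typing,2022,99.9
LOW,Molecular typing,2011,99.0
LOW,Molecular typing,2012,98.9
LOW,Molecular typing,2013,99.0
LOW,Molecular typing,2014,99.5
LOW,Molecular typing,2015,99.2
LOW,Molecular typing,2016,99.3
LOW,Molecular typing,2017,99.2
LOW,Molecular typing,2018,99.8
LOW,Molecular typing,2019,99.8
LOW,Molecular typing,2020,99.6
LOW,Molecular typing,2021,99.8
LOW,Molecular typing,2022,99.9
B57,Molecular typing,2012,98.8
B57,Molecular typing,2013,99.5
B57,Molecular typing,2014,99.7
B57,Molecular typing,2015,100.0
B57,Molecular typing,2016,98.1
B57,Molecular typing,2017,100.0
B57,Molecular typing,2018,98.8
B57,Molecular typing,2019,99.0
B57,Molecular typing,2020,99.9
B57,Molecular typing,2021,99.2
B57,Molecular typing,2022,99.8
HI,Molecular typing,2011,99.0
HI,Molecular typing,2012,99.0
HI,Molecular typing,2013,99.1
HI,Molecular typing,2014,99.5
HI,Molecular typing,2015,99.3
HI,Molecular typing,2016,99.6
HI,Molecular typing,2017,98.7
HI,Molecular typing,2018,99.1
HI,Molecular typing,2019,99.1
HI,Molecular typing,2020,99.0
HI,Molecular typing,2021,98.0
HI,Molecular typing,2022,98.6
B27,Molecular typing,2011,99.5
B27,Molecular typing,2012,99.5
B27,Molecular typing,2013,95.7
B27,Molecular typing,2014,99.3
B27,Molecular typing,2015,98.9
B27,Molecular typing,2016,99.3
B27,Molecular typing,2017,98.7
B27,Molecular typing,2018,98.4
B27,Molecular typing,2019,99.8
B27,Molecular typing,2020,99.5
B27,Molecular typing,2021,99.2
B27,Molecular typing,2022,99.9
CD,Molecular typing,2012,96.8
CD,Molecular typing,2013,99.1
CD,Molecular typing,2014,99.3
CD,Molecular typing,2015,99.3
CD,Molecular typing,2016,95.3
CD,Molecular typing,2017,98.9
CD,Molecular typing,2018,97.8
CD,Molecular typing,2019,98.1
CD,Molecular typing,2020,98.8
CD,Molecular typing,2021,98.4
CD,Molecular typing,2022,99.6
AHPA,Antibodies,2019,100.0
AHPA,Antibodies,2020,98.3
AHPA,Antibodies,2021,99.3
AHPA,Antibodies,2022,100.0
ALO,Antibodies,2011,97.7
ALO,Antibodies,2012,98.7
ALO,Antibodies,2013,99.1
ALO,Antibodies,2014,98.7
ALO,Antibodies,2015,98.3
ALO,Antibodies,2016,98.6
ALO,Antibodies,2017,99.8
ALO,Antibodies,2018,99.4
ALO,Antibodies,2019,99.3
ALO,Antibodies,2020,99.5
ALO,Antibodies,2021,99.3
ALO,Antibodies,2022,99.7
SER,Serology,2011,96.2
SER,Serology,2012,96.0
SER,Serology,2013,98.9
SER,Serology,2014,99.6
SER,Serology,2015,99.4
SER,Serology,2016,99.8
SER,Serology,2017,99.7
SER,Serology,2018,99.5
SER,Serology,2019,99.3
SER,Serology,2020,99.3
SER,Serology,2021,99.3
SER,Serology,2022,100.0
XM,Crossmatch,2011,96.2
XM,Crossmatch,2012,97.2
XM,Crossmatch,2013,97.4
XM,Crossmatch,2014,97.5
XM,Crossmatch,2015,97.3
XM,Crossmatch,2016,95.0
XM,Crossmatch,2017,99.2
XM,Crossmatch,2018,99.3
XM,Crossmatch,2019,98.3
XM,Crossmatch,2020,99.6
XM,Crossmatch,2021,96.6
XM,Crossmatch,2022,99.2
XMFC,Crossmatch,2012,94.9
XMFC,Crossmatch,2013,94.7
XMFC,Crossmatch,2014,97.3
XMFC,Crossmatch,2015,95.1
XMFC,Crossmatch,2016,94.1
XMFC,Crossmatch,2017,95.2
XMFC,Crossmatch,2018,94.5
XMFC,Crossmatch,2019,95.4
XMFC,Crossmatch,2020,97.1
XMFC,Crossmatch,2021,95.3
XMFC,Crossmatch,2022,97.8
CHM,Chimerism,2013,88.2
CHM,Chimerism,2014,92.1
CHM,Chimerism,2015,97.0
CHM,Chimerism,2016,95.8
CHM,Chimerism,2017,96.4
CHM,Chimerism,2018,94.6
CHM,Chimerism,2019,93.8
CHM,Chimerism,2020,96.6
CHM,Chimerism,2021,95.7
CHM,Chimerism,2022,97.8
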
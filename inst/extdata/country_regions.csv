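country,region
US,North America
CA,North America
MX,North America
FR,Europe
DE,Europe
IT,Europe
GB,Europe
ES,Europe
NL,Europe
BE,Europe
CH,Europe
SE,Europe
PL,Europe
PT,Europe
JP,Asia
CN,Asia
IN,Asia
KR,Asia
TW,Asia
TH,Asia
IL,Asia
AU,Oceania
NZ,Oceania
BR,South America
AR,South America
CO,South America
CL,South America
ZA,Africa
EG,Africa
NG,Africa
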
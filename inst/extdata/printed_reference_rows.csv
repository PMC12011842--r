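ingredient_key,a,ror,ci_low,ci_high,prr,chi2
metformin,16439,252.24,246.74,257.87,234.15,1903496.45
lamivudine/stavudine,4,144.62,52.01,402.13,132.89,523.86
electrolytes nos,3,119.04,36.86,384.44,110.99,327.18
lamivudine/nevirapine/stavudine,36,97.71,69.79,136.80,92.24,3247.35
sodium acetate,3,78.72,24.71,250.79,75.13,219.56
stavudine,208,76.21,66.29,87.61,72.86,14657.68
pentobarbital,10,55.92,29.77,105.04,54.09,521.29
nitroprusside,9,52.12,26.83,101.22,50.53,437.10
didanosine,106,49.10,40.46,59.58,47.70,4833.32
linezolid,815,39.96,37.25,42.87,39.05,29482.30
benzoic acid/sodium phenylacetate,5,39.88,16.42,96.84,38.95,184.95
amprenavir,3,36.70,11.69,115.24,35.91,101.87
glycine,3,35.37,11.27,111.02,34.64,98.05
telbivudine,80,35.11,28.13,43.83,34.40,2589.19
vasopressin,9,27.32,14.14,52.80,26.89,224.40
alogliptin/metformin,9,27.07,14.01,52.31,26.64,222.20
indinavir,26,25.23,17.12,37.16,24.86,595.18
zidovudine,175,23.38,20.13,27.15,23.06,3675.71
saquinavir,21,23.29,15.13,35.83,22.97,441.29
terbutaline,11,22.43,12.37,40.67,22.14,222.10
linagliptin/metformin,19,22.33,14.20,35.12,22.04,381.64
metformin/pioglitazone,17,21.79,13.50,35.16,21.51,332.52
nelfinavir,24,17.28,11.56,25.84,17.11,363.96
glibenclamide/metformin,19,17.19,10.94,27.02,17.02,286.52
gliclazide,3,16.43,5.27,51.25,16.28,43.04
metformin/sitagliptin,248,16.19,14.28,18.36,16.05,3474.46
hydroxocobalamin,6,15.18,6.79,33.92,15.05,78.74
tebentafusp,7,13.91,6.61,29.27,13.80,83.12
repaglinide,27,13.85,9.48,20.24,13.74,319.00
emtricitabine,16,13.85,8.47,22.66,13.74,189.07
enalapril/hydrochlorothiazide,11,13.23,7.31,23.95,13.13,123.31
tedizolid,8,12.98,6.47,26.03,12.88,87.72
glimepiride,78,12.76,10.21,15.95,12.67,837.12
metformin/vildagliptin,66,12.24,9.61,15.60,12.16,675.06
glibenclamide,43,11.80,8.74,15.93,11.72,421.28
entecavir,67,11.63,9.14,14.79,11.55,644.89
nevirapine,130,11.50,9.67,13.66,11.42,1232.06
carglumic acid,11,11.36,6.28,20.55,11.29,103.15
efavirenz,87,11.17,9.05,13.80,11.11,798.35
empagliflozin/metformin,31,11.15,7.83,15.88,11.08,284.19
amlodipine/perindopril,9,11.14,5.79,21.47,11.08,82.52
abacavir,45,10.65,7.94,14.28,10.58,390.26
cimetidine,16,9.95,6.08,16.26,9.89,127.91
capivasertib,4,9.77,3.66,26.11,9.72,31.30
propofol,127,9.44,7.93,11.25,9.39,949.42
norepinephrine,24,9.29,6.22,13.87,9.24,176.32
fosamprenavir,10,8.41,4.52,15.66,8.37,64.93
colchicine,55,8.04,6.17,10.48,8.01,336.95
dapagliflozin/metformin,20,7.75,4.99,12.03,7.72,116.96
hydrochlorothiazide/irbesartan,35,7.49,5.38,10.45,7.46,195.84
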
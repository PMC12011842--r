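verbatim,ingredient_key
glucophage,metformin
zyvox,linezolid
lipitor,atorvastatin
ventolin,salbutamol
tylenol,paracetamol
norvasc,amlodipine
zerit,stavudine
viramune,nevirapine
sebivo,telbivudine
diprivan,propofol
janumet,metformin/sitagliptin
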
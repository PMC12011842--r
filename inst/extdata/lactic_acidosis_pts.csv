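pt_code,pt_name
10005635,Blood lactic acid increased
10020660,Hyperlactacidaemia
10023676,Lactic acidosis
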
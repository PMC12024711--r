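treatment,n,deaths,grade5
OBS,45546,2953,2000
SPLENECTOMY,7128,1426,2033
AE,1671,157,253
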
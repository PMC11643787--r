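symbol,ip_ev,ea_ev,r_cov_a,logp_contrib,valence
H,13.598,0.754,0.31,0.123,1
C,11.260,1.262,0.76,0.271,4
N,14.534,-0.070,0.71,-0.600,3
O,13.618,1.461,0.66,-0.397,2
S,10.360,2.077,1.05,0.255,2
P,10.487,0.746,1.07,-0.447,3
F,17.423,3.401,0.57,0.398,1
Cl,12.968,3.613,1.02,0.663,1
Br,11.814,3.364,1.20,0.860,1
I,10.451,3.059,1.39,1.272,1
B,8.298,0.280,0.84,-0.200,3
Si,8.152,1.385,1.11,0.200,4
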
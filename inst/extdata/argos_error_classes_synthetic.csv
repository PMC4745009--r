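lc,tau_x,tau_y,nu
3,0.29,0.17,4.0
2,0.32,0.24,3.0
1,0.51,0.49,2.0
0,1.55,1.25,1.5
A,0.84,0.52,2.0
B,1.56,1.04,1.2
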
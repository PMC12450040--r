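delta_d,delta_p,delta_h,R0,rms
15.79671566,0.05858518418,0.1581312362,10.05301016,0.002380585424
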
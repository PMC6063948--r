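stop_id,stop_name,stop_lon,stop_lat
A,Alpha,0.00,0.00
B,Bravo,0.10,0.02
C,Charlie,0.21,0.01
D,Delta,0.30,0.03
E,Echo,0.41,0.02
F,Foxtrot,0.52,0.00
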
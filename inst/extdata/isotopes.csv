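# Bound coherent neutron scattering lengths, fm
# source: Sears, Neutron News 3 (1992) 26-37
isotope,b_coh_fm
H,-3.7390
D,6.6710
C,6.6460
N,9.3600
O,5.8030
P,5.1300
Na,3.6300
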
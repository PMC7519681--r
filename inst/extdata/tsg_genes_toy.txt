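Trp53
Pbrm1
Prdm2
Esrp1
Apc
Nf1
Atm
Rasal1
Csmd1
Slit2
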
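Plekha5
Arhgef11
Adam20
Ttn
Ttc28
Kansl2
Ipo7
Stx3
Top1
Adh5
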
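Nras
Kras
Egfr
Akt3
Yy1
Rere
Tpr
Aff3
Kdr
Psip1
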
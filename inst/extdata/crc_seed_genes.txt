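# known CRC predisposition genes (seed list)
MLH1
MSH2
MSH3
MSH6
MUTYH
NTHL1
PMS2
POLD1
POLE
BMPR1A
SMAD4
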
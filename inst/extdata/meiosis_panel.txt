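REC8
SYCP3
HORMAD1
TEX12
MSH4
SYCP1
SYCP2
SYCE1
SYCE2
SYCE3
SIX6OS1
SPO11
DMC1
MEIOB
SPATA22
MND1
PSMC3IP
STAG3
SMC1B
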
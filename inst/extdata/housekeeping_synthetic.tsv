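gene
ACTB
GAPDH
B2M
TUBB
RPL13A
RPS18
PPIA
HPRT1
TBP
GUSB
PGK1
PPIB
RPLP0
SDHA
UBC
YWHAZ
EEF1A1
RPL19
RPS11
RPL27
RPS27A
RPL9
RPS3
RPL11
EIF4A2
HNRNPC
PABPC1
SRSF3
NACA
BTF3
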
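CMC
SFL
PCS
LFF
FSM
MSMF
CLMP
PPSL
FLCM
SCPC
CSPLL
LFPSS
PFMLM
MLCFP
SPMCF
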
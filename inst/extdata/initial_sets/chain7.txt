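RLB
VBF
LFR
GGV
BRG
RBGL
LFBV
VLGG
GFLL
FGLB
GBVRF
BLVFF
LVRRB
RVFBR
FVGRV
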
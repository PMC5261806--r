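VSB
SGT
GTV
BVT
TBZ
VBSS
GZTB
STGS
TZBT
ZVTG
BZTSV
VBGSZ
GVVZG
SSGBB
ZGZVZ
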
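SRS
ZPR
MRL
RZM
LMZ
RRZR
LPMP
PLRM
ZSMM
SLSP
PZPSS
MLZRL
RPMPZ
SZLLZ
LSMSP
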
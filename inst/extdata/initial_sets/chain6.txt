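PCH
NVP
VNC
HPV
TCN
NPTN
TVTP
HCNT
CTHV
PHHC
NHTCT
TVHPH
HVPCV
CPNNC
VCVNP
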
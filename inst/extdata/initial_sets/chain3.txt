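SLW
LXS
CWC
WSX
XKK
LSWK
CCCX
KXKL
SXLC
WKXL
KSKCW
SWCLX
WLSCS
LWXSC
XWLKW
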